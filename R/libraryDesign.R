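## Mutant library enumeration: saturation single-point scans, compensatory
## double-point scans, deletion variants.  RNA alphabet {A,C,G,U};
## coordinates 1-based on the reference sequence.

.RNA_BASES <- c("A", "C", "G", "U")
.PURINES <- c("A", "G")

## The three alternatives to a base, transition first, then the two
## transversions in alphabetical order (fixed emission order so enumerations
## are reproducible).
.BASE_ALTERNATIVES <- list(
  A = c("G", "C", "U"),
  C = c("U", "A", "G"),
  G = c("A", "C", "U"),
  U = c("C", "A", "G"))

.WC_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")

.asRNAString <- function(seq) {
  if (is(seq, "RNAString")) return(seq)
  if (is.character(seq)) {
    s <- gsub("T", "U", toupper(seq))
    bad <- setdiff(unique(strsplit(s, "")[[1]]), .RNA_BASES)
    if (length(bad))
      .stopf("sequence contains non-{A,C,G,U} characters: %s",
             paste(bad, collapse = ", "))
    return(RNAString(s))
  }
  .stopf("expected an RNAString or a character string")
}

.checkAlphabet <- function(seq) {
  ch <- strsplit(as.character(seq), "")[[1]]
  bad <- setdiff(unique(ch), .RNA_BASES)
  if (length(bad))
    .stopf("sequence contains non-{A,C,G,U} characters: %s",
           paste(bad, collapse = ", "))
  ch
}

#' Classify a point substitution as transition or transversion
#'
#' Transitions exchange purine for purine (A/G) or pyrimidine for pyrimidine
#' (C/U); transversions cross the two classes.
#'
#' @param wt,alt character vectors of single bases.
#' @return character vector, `"transition"` or `"transversion"`.
#' @export
#' @examples
#' mutationClass(c("A", "A"), c("G", "C"))
mutationClass <- function(wt, alt) {
  stopifnot(length(wt) == length(alt))
  if (any(wt == alt)) .stopf("wt and alt base must differ")
  ifelse((wt %in% .PURINES) == (alt %in% .PURINES),
         "transition", "transversion")
}

## Build the mutants DataFrame from parallel per-substitution vectors.
## grpWidths gives substitutions per mutant (0 allowed for WT/controls).
.mutantTable <- function(ids, widths, pos, wt, alt,
                         deletions = NULL, isWT = NULL, isControl = NULL) {
  nm <- length(ids)
  part <- IRanges::PartitioningByWidth(widths)
  if (is.null(deletions)) deletions <- IntegerList(rep(list(integer()), nm))
  if (is.null(isWT)) isWT <- widths == 0L & lengths(deletions) == 0L
  if (is.null(isControl)) isControl <- rep(FALSE, nm)
  DataFrame(
    id = ids,
    pos = IRanges::relist(as.integer(pos), part),
    wt = IRanges::relist(wt, part),
    alt = IRanges::relist(alt, part),
    mutClass = IRanges::relist(
      if (length(pos)) mutationClass(wt, alt) else character(), part),
    deletions = deletions,
    isWT = isWT,
    isControl = isControl)
}

#' Enumerate all single-point mutants of a reference sequence
#'
#' Produces the saturation scan: three substitutions per position (the one
#' transition and the two transversions), in deterministic order (position,
#' then transition first, transversions alphabetically).  An 87-nt reference
#' yields 261 single-point mutants (SPMs).
#'
#' @param seq reference sequence ([Biostrings::RNAString] or character;
#'   `T` is read as `U`).
#' @return a [MutantLibrary] with `3 * length(seq)` SPMs.
#' @seealso [enumerateCompensatoryDPMs()], [applyMutations()]
#' @export
#' @examples
#' lib <- enumerateSPMs("ACGU")
#' mutantIds(lib)
enumerateSPMs <- function(seq) {
  seq <- .asRNAString(seq)
  ref <- .checkAlphabet(seq)
  n <- length(ref)
  pos <- rep(seq_len(n), each = 3L)
  wt <- ref[pos]
  alt <- unlist(.BASE_ALTERNATIVES[ref], use.names = FALSE)
  ids <- paste0(wt, pos, alt)
  new("MutantLibrary", refSeq = seq,
      mutants = .mutantTable(ids, rep(1L, 3L * n), pos, wt, alt))
}

#' Enumerate compensatory double-point mutants
#'
#' For every unordered position pair, emits three double-point mutants
#' (DPMs): the k-th alternative of the first base combined with the k-th
#' alternative of the second base (alternatives ordered transition first,
#' transversions alphabetically), i.e. the three joint re-pairings of the
#' pair.  The complete scan over an n-nt sequence has `3 * choose(n, 2)`
#' DPMs — 11223 for an 87-nt reference.
#'
#' When `pairingMap` lists known stem pairs, the second substitution of each
#' DPM at those pairs is instead the Watson-Crick complement of the first
#' substitution, producing the pairing-restoring rescue set used in stem
#' screens.
#'
#' @param seq reference sequence.
#' @param pairs optional 2-column matrix (or list of length-2 vectors) of
#'   1-based position pairs; default: all unordered pairs.
#' @param pairingMap optional 2-column matrix of base-paired positions; for
#'   pairs present in the map the partner substitution restores Watson-Crick
#'   complementarity.
#' @return a [MutantLibrary] of DPMs (ids like `"A12G+A15G"`).
#' @export
#' @examples
#' lib <- enumerateCompensatoryDPMs("ACG")
#' length(mutantIds(lib))  # 3 * choose(3, 2) = 9
enumerateCompensatoryDPMs <- function(seq, pairs = NULL, pairingMap = NULL) {
  seq <- .asRNAString(seq)
  ref <- .checkAlphabet(seq)
  n <- length(ref)
  if (is.null(pairs)) {
    if (n < 2L) .stopf("need at least 2 positions for a DPM scan")
    pairs <- t(combn(n, 2L))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, lapply(pairs, as.integer))
  } else {
    pairs <- matrix(as.integer(pairs), ncol = 2L)
  }
  if (length(pairs) == 0L) {
    return(new("MutantLibrary", refSeq = seq,
               mutants = .mutantTable(character(), integer(),
                                      integer(), character(), character())))
  }
  if (any(pairs[, 1L] == pairs[, 2L]))
    .stopf("invalid pair: the two positions of a DPM must differ")
  if (any(pairs < 1L) || any(pairs > n))
    .stopf("pair position out of bounds (sequence length %d)", n)
  ## canonical order i < j
  i <- pmin(pairs[, 1L], pairs[, 2L])
  j <- pmax(pairs[, 1L], pairs[, 2L])
  P <- length(i)
  cls <- rep(1:3, times = P)
  ii <- rep(i, each = 3L)
  jj <- rep(j, each = 3L)
  wt1 <- ref[ii]; wt2 <- ref[jj]
  alt1 <- vapply(seq_along(ii),
                 function(k) .BASE_ALTERNATIVES[[wt1[k]]][cls[k]], "")
  alt2 <- vapply(seq_along(jj),
                 function(k) .BASE_ALTERNATIVES[[wt2[k]]][cls[k]], "")
  if (!is.null(pairingMap)) {
    pairingMap <- matrix(as.integer(pairingMap), ncol = 2L)
    key <- paste(pmin(pairingMap[, 1L], pairingMap[, 2L]),
                 pmax(pairingMap[, 1L], pairingMap[, 2L]))
    inMap <- paste(ii, jj) %in% key
    alt2[inMap] <- .WC_COMPLEMENT[alt1[inMap]]
    drop <- inMap & (alt2 == wt2)   # rescue partner equals wt: not a DPM
    if (any(drop)) {
      keep <- !drop
      ii <- ii[keep]; jj <- jj[keep]
      wt1 <- wt1[keep]; wt2 <- wt2[keep]
      alt1 <- alt1[keep]; alt2 <- alt2[keep]
    }
  }
  ids <- paste0(wt1, ii, alt1, "+", wt2, jj, alt2)
  m <- length(ids)
  pos <- as.vector(rbind(ii, jj))
  wt <- as.vector(rbind(wt1, wt2))
  alt <- as.vector(rbind(alt1, alt2))
  new("MutantLibrary", refSeq = seq,
      mutants = .mutantTable(ids, rep(2L, m), pos, wt, alt))
}

#' Parse a mutation label into a specification
#'
#' Understands substitution tokens (`"U50C"`), single-base deletion tokens
#' (`"U50D"`), named deletion regions (keys of `regions`, e.g. `"KD"` for a
#' knob deletion), and `+`-joined combinations (`"A12G+A15G+U50D"`).  `"WT"`
#' is the empty specification.
#'
#' @param label character label.
#' @param refSeq reference sequence (for wt-base verification).
#' @param regions named list of integer vectors: named deletion regions.
#' @return list with `pos`, `wt`, `alt` (substitutions) and `deletions`.
#' @export
#' @examples
#' parseMutationLabel("A1G+C2D", "ACGU")
parseMutationLabel <- function(label, refSeq, regions = list()) {
  ref <- .checkAlphabet(.asRNAString(refSeq))
  out <- list(pos = integer(), wt = character(), alt = character(),
              deletions = integer())
  if (identical(label, "WT") || !nzchar(label)) return(out)
  for (tok in strsplit(label, "+", fixed = TRUE)[[1]]) {
    if (tok %in% names(regions)) {
      out$deletions <- c(out$deletions, as.integer(regions[[tok]]))
      next
    }
    m <- regmatches(tok, regexec("^([ACGU])([0-9]+)([ACGUD])$", tok))[[1]]
    if (length(m) != 4L)
      .stopf("cannot parse mutation token '%s'", tok)
    p <- as.integer(m[3])
    if (p < 1L || p > length(ref))
      .stopf("token '%s': position %d out of bounds", tok, p)
    if (ref[p] != m[2])
      .stopf("token '%s': reference has '%s' at position %d", tok, ref[p], p)
    if (m[4] == "D") {
      out$deletions <- c(out$deletions, p)
    } else {
      out$pos <- c(out$pos, p)
      out$wt <- c(out$wt, m[2])
      out$alt <- c(out$alt, m[4])
    }
  }
  out$deletions <- sort(unique(out$deletions))
  out
}

#' Build a mutant library from labels
#'
#' @param refSeq reference sequence.
#' @param labels character vector of mutation labels (see
#'   [parseMutationLabel()]); `"WT"` allowed.
#' @param regions named list of deletion regions.
#' @param controls character vector of labels to flag as controls (e.g. the
#'   empty-core negative control, which carries no aptamer sequence).
#' @return a [MutantLibrary].
#' @export
#' @examples
#' newMutantLibrary("ACGU", c("WT", "A1G", "C2U+G3C"))
newMutantLibrary <- function(refSeq, labels, regions = list(),
                             controls = character()) {
  seq <- .asRNAString(refSeq)
  specs <- lapply(labels, parseMutationLabel, refSeq = seq, regions = regions)
  widths <- vapply(specs, function(s) length(s$pos), 0L)
  new("MutantLibrary", refSeq = seq,
      mutants = .mutantTable(
        ids = labels, widths = widths,
        pos = unlist(lapply(specs, `[[`, "pos")),
        wt = unlist(lapply(specs, `[[`, "wt")),
        alt = unlist(lapply(specs, `[[`, "alt")),
        deletions = IntegerList(lapply(specs, `[[`, "deletions")),
        isControl = labels %in% controls))
}

#' Apply a mutant specification to a sequence
#'
#' Substitutions are applied first (each checked against the reference base,
#' guarding against coordinate drift), then deletion positions are removed.
#' The resulting length is `length(seq) - length(deletions)`.
#'
#' @param seq reference sequence.
#' @param substitutions character vector of substitution tokens (`"U50C"`)
#'   or a list as returned by [parseMutationLabel()].
#' @param deletions integer vector of 1-based positions to delete.
#' @return the mutated [Biostrings::RNAString].
#' @seealso [applyMutations()] for whole-library application.
#' @export
#' @examples
#' mutateSequence("ACGU", "A1G")
#' mutateSequence("ACGU", character(), deletions = 2:3)
mutateSequence <- function(seq, substitutions = character(),
                           deletions = integer()) {
  seq <- .asRNAString(seq)
  ref <- .checkAlphabet(seq)
  if (is.list(substitutions)) {
    spec <- substitutions
    deletions <- union(as.integer(deletions), spec$deletions)
  } else {
    spec <- parseMutationLabel(
      if (length(substitutions)) paste(substitutions, collapse = "+") else "WT",
      seq)
  }
  if (length(spec$pos)) {
    if (any(spec$pos < 1L | spec$pos > length(ref)))
      .stopf("substitution position out of bounds")
    mism <- ref[spec$pos] != spec$wt
    if (any(mism))
      .stopf("reference mismatch at position %d: expected '%s', found '%s'",
             spec$pos[mism][1], spec$wt[mism][1], ref[spec$pos[mism][1]])
    ref[spec$pos] <- spec$alt
  }
  deletions <- as.integer(deletions)
  if (length(deletions)) {
    if (any(deletions < 1L | deletions > length(ref)))
      .stopf("deletion position out of bounds")
    ref <- ref[-deletions]
  }
  RNAString(paste(ref, collapse = ""))
}

#' Materialise mutant sequences from a library
#'
#' @param x a [MutantLibrary].
#' @param ids mutant ids to materialise (default: all).
#' @return a named [Biostrings::RNAStringSet].
#' @export
#' @examples
#' lib <- enumerateSPMs("ACGU")
#' applyMutations(lib, c("A1G", "U4C"))
applyMutations <- function(x, ids = mutantIds(x)) {
  stopifnot(is(x, "MutantLibrary"))
  m <- x@mutants
  idx <- match(ids, m$id)
  if (anyNA(idx)) .stopf("unknown mutant id: %s", ids[is.na(idx)][1])
  seqs <- vapply(idx, function(k) {
    as.character(mutateSequence(
      x@refSeq,
      list(pos = m$pos[[k]], wt = m$wt[[k]], alt = m$alt[[k]],
           deletions = integer()),
      deletions = m$deletions[[k]]))
  }, "")
  RNAStringSet(setNames(seqs, ids))
}

#' Subset a mutant library
#'
#' @param x a [MutantLibrary].
#' @param i mutant ids (character) or indices.
#' @param j,drop,... ignored.
#' @return a [MutantLibrary].
#' @export
setMethod("[", "MutantLibrary", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@mutants$id)
  if (anyNA(i)) .stopf("unknown mutant id in subset")
  initialize(x, mutants = x@mutants[i, , drop = FALSE])
})

#' Combine mutant libraries over the same reference
#'
#' @param x,... [MutantLibrary] objects sharing one reference sequence.
#' @return a [MutantLibrary].
#' @export
setMethod("c", "MutantLibrary", function(x, ...) {
  more <- list(...)
  for (y in more) {
    if (as.character(y@refSeq) != as.character(x@refSeq))
      .stopf("cannot combine libraries with different references")
  }
  new("MutantLibrary", refSeq = x@refSeq,
      mutants = do.call(rbind, c(list(x@mutants),
                                 lapply(more, function(y) y@mutants))))
})
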