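## Two-fragment assembly design.  Each mutant sequence is split into a 5'
## and a 3' fragment sharing an exact overlap (default 19 nt, mirroring
## two-oligo stitch PCR); the 5' fragment additionally carries opaque tag
## sequences (T7 promoter, pull-down anchor, detection probe), supplied via
## config since the tags themselves are assay-specific.

#' Default fragment-design configuration
#'
#' @param overlapLen overlap length in nt (default 19).
#' @param promoter,anchor,probe tag sequences prepended to the 5' fragment
#'   (opaque strings; empty by default).
#' @return named list.
#' @export
fragmentConfig <- function(overlapLen = 19L, promoter = "", anchor = "",
                           probe = "") {
  list(overlapLen = as.integer(overlapLen), promoter = promoter,
       anchor = anchor, probe = probe)
}

#' Design the two-fragment assembly for a mutant
#'
#' Splits `mutantSeq` so that the two fragments share an `overlapLen`-nt
#' region centred on the sequence midpoint.  `mutationPositions` (1-based on
#' the mutant sequence) determine which fragment(s) must carry the mutant
#' oligo: positions left of the overlap give `"5prime"`, right of it
#' `"3prime"`, inside it (or straddling both sides) `"both"`, and no
#' mutations give `"none"` (wild-type fragments).
#'
#' @param mutantSeq the mutant sequence (RNA sense).
#' @param mutationPositions integer positions of the mutated bases.
#' @param config see [fragmentConfig()].
#' @return a [FragmentDesign].
#' @seealso [stitchFragments()] for the inverse operation.
#' @export
#' @examples
#' fd <- designFragments(paste(rep("ACGU", 10), collapse = ""), 5,
#'                       fragmentConfig(overlapLen = 8))
#' fd@placement
designFragments <- function(mutantSeq, mutationPositions = integer(),
                            config = fragmentConfig()) {
  seq <- as.character(.asRNAString(mutantSeq))
  n <- nchar(seq)
  ov <- config$overlapLen
  if (ov >= n) .stopf("overlap length (%d) must be < sequence length (%d)",
                      ov, n)
  mutationPositions <- as.integer(mutationPositions)
  if (length(mutationPositions) &&
      (any(mutationPositions < 1L) || any(mutationPositions > n)))
    .stopf("mutation position out of sequence bounds [1, %d]", n)
  splitAt <- (n + ov) %/% 2L          # last position covered by fragment5
  ovStart <- splitAt - ov + 1L        # overlap = [ovStart, splitAt]
  frag5 <- substring(seq, 1L, splitAt)
  frag3 <- substring(seq, ovStart, n)
  in5 <- mutationPositions < ovStart
  in3 <- mutationPositions > splitAt
  inOv <- !in5 & !in3
  placement <- if (!length(mutationPositions)) "none"
    else if (any(inOv) || (any(in5) && any(in3))) "both"
    else if (any(in5)) "5prime" else "3prime"
  new("FragmentDesign",
      fragment5 = frag5, fragment3 = frag3,
      tags = config[c("promoter", "anchor", "probe")],
      overlapLen = ov, splitAt = splitAt, placement = placement)
}

#' Reassemble a mutant sequence from its fragment design
#'
#' The inverse of [designFragments()]: verifies that the two fragments agree
#' on the overlap and concatenates them.  `stitchFragments(designFragments(s,
#' ...))` reproduces `s` exactly.
#'
#' @param design a [FragmentDesign].
#' @return the reassembled [Biostrings::RNAString].
#' @export
stitchFragments <- function(design) {
  stopifnot(is(design, "FragmentDesign"))
  validObject(design)
  RNAString(paste0(design@fragment5,
                   substring(design@fragment3, design@overlapLen + 1L)))
}

#' Full-length 5' oligo including tags
#'
#' @param design a [FragmentDesign].
#' @return character: promoter + anchor + probe tags followed by the 5'
#'   template region.
#' @export
taggedFragment5 <- function(design) {
  paste0(design@tags$promoter, design@tags$anchor, design@tags$probe,
         design@fragment5)
}
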