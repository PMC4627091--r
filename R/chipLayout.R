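## Chip layout planning: assign mutants x replicates to unit cells of a
## microfluidic chip (default 640 cells, 4 replicates -> capacity 160
## mutants including controls).

#' Plan a chip layout
#'
#' Assigns each mutant to exactly `replicates` unit cells.  The default
#' assignment is deterministic (mutants in input order, replicates in
#' consecutive cells); `seed` requests a seeded shuffle of cell order
#' instead, so replicate spots are dispersed across the chip.
#'
#' @param mutantIds character vector of mutant ids (controls included in the
#'   count; pass them here like any other id).
#' @param nCells number of functional unit cells (default 640).
#' @param replicates repeats per mutant (default 4).
#' @param controls subset of `mutantIds` flagged as control cells.
#' @param nColumns number of columns used to lay cells out on a grid
#'   (cosmetic; rows/cols are derived from the cell index).
#' @param seed optional integer; seeded random placement.
#' @return a [ChipLayout].
#' @export
#' @examples
#' planChipLayout(c("WT", "A1G", "NEG"), nCells = 16, replicates = 4,
#'                controls = c("WT", "NEG"))
planChipLayout <- function(mutantIds, nCells = 640L, replicates = 4L,
                           controls = character(), nColumns = 20L,
                           seed = NULL) {
  nCells <- as.integer(nCells)
  replicates <- as.integer(replicates)
  if (replicates < 1L) .stopf("replicates must be >= 1")
  if (anyDuplicated(mutantIds)) .stopf("mutant ids must be unique")
  need <- length(mutantIds) * replicates
  if (need > nCells)
    .stopf(paste0("over capacity: %d mutants x %d replicates needs %d ",
                  "cells but the chip has %d (capacity %d mutants)"),
           length(mutantIds), replicates, need, nCells,
           nCells %/% replicates)
  cells <- seq_len(need)
  if (!is.null(seed))
    cells <- withLocalSeed(seed, sample(seq_len(nCells), need))
  assignment <- data.frame(
    cell = cells,
    row = (cells - 1L) %/% nColumns + 1L,
    col = (cells - 1L) %% nColumns + 1L,
    mutant_id = rep(mutantIds, each = replicates),
    replicate = rep(seq_len(replicates), times = length(mutantIds)),
    control = rep(mutantIds %in% controls, each = replicates),
    stringsAsFactors = FALSE)
  new("ChipLayout", nCells = nCells, replicates = replicates,
      assignment = assignment)
}
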