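# Puff-to-cigarette aggregation.
#
# Consecutive SPMs are grouped into whole-cigarette events: a gap of more
# than 10 minutes between the end of one SPM and the start of the next
# splits the sequence into separate cigarettes, and groups with fewer
# SPMs than the minimum count (2) are discarded as spurious.

#' Aggregation configuration
#'
#' @param gap_s split threshold in seconds; a strictly larger idle gap
#'   between consecutive SPMs starts a new cigarette (default 600 s,
#'   i.e. 10 min).
#' @param min_spm_count minimum SPMs per cigarette; smaller groups are
#'   discarded (default 2).
#' @return an object of class `aggregation_config`.
#' @export
aggregation_config <- function(gap_s = 600, min_spm_count = 2) {
  stopifnot(gap_s > 0, min_spm_count >= 1)
  structure(list(gap_s = gap_s, min_spm_count = as.integer(min_spm_count)),
            class = "aggregation_config")
}

#' Group consecutive SPMs into cigarette events
#'
#' @param spms an [spm_events()] table (or any data frame with `start_s`
#'   and `end_s`), sorted by `start_s` and non-overlapping.
#' @param config an [aggregation_config()].
#' @return data frame of class `cigarette_events` with one row per
#'   cigarette: `start_s` (first SPM start), `end_s` (last SPM end),
#'   `n_spm`, and a list column `spms` holding each group's member SPMs.
#' @export
group_cigarettes <- function(spms, config = aggregation_config()) {
  if (nrow(spms) == 0L) return(empty_cigarettes())
  if (is.unsorted(spms$start_s)) {
    stop("group_cigarettes: SPMs must be sorted by start_s")
  }
  if (nrow(spms) > 1L &&
      any(spms$start_s[-1L] < spms$end_s[-nrow(spms)])) {
    stop("group_cigarettes: SPMs must not overlap")
  }
  gap <- spms$start_s[-1L] - spms$end_s[-nrow(spms)]
  grp <- cumsum(c(1L, as.integer(gap > config$gap_s)))
  pieces <- split(seq_len(nrow(spms)), grp)
  pieces <- pieces[vapply(pieces, length, integer(1)) >= config$min_spm_count]
  if (length(pieces) == 0L) return(empty_cigarettes())
  out <- data.frame(
    start_s = vapply(pieces, function(ix) spms$start_s[ix[1L]], numeric(1)),
    end_s = vapply(pieces, function(ix) spms$end_s[ix[length(ix)]],
                   numeric(1)),
    n_spm = vapply(pieces, length, integer(1)))
  out$spms <- lapply(pieces, function(ix) spms[ix, , drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("cigarette_events", "data.frame")
  out
}

empty_cigarettes <- function() {
  out <- data.frame(start_s = numeric(), end_s = numeric(),
                    n_spm = integer())
  out$spms <- list()
  class(out) <- c("cigarette_events", "data.frame")
  out
}
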