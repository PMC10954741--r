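## Final per-cell labels: posterior and restart-consistency thresholds with
## an explicit "unassigned" state.

#' Labeling thresholds
#'
#' A cell is assigned to its maximum-posterior clone only when that
#' posterior reaches `min_posterior` (default 0.8) and the cell's assignment
#' is consistent across at least `min_consistency` (default 0.7) of the
#' repeated runs; otherwise it is `"unassigned"`.
#'
#' @param min_posterior minimum clone-assignment probability.
#' @param min_consistency minimum across-restart agreement fraction.
#' @return a `labeling_config` list.
#' @export
labeling_config <- function(min_posterior = 0.8, min_consistency = 0.7) {
  stopifnot(min_posterior > 0, min_posterior <= 1,
            min_consistency > 0, min_consistency <= 1)
  structure(list(min_posterior = min_posterior,
                 min_consistency = min_consistency),
            class = "labeling_config")
}

#' Assign per-cell clone labels
#'
#' @param posterior N x C row-stochastic posterior matrix with clone column
#'   names.
#' @param consistency per-cell across-restart agreement fraction (scalar is
#'   recycled; default 1, i.e. no consistency information).
#' @param config a [labeling_config()].
#' @return character vector of labels in `colnames(posterior)` or
#'   `"unassigned"`. Argmax ties are broken by the first clone in column
#'   order (at two clones a tie gives posterior 0.5 and is therefore
#'   unassigned under the default threshold anyway).
#' @export
assign_labels <- function(posterior, consistency = 1,
                          config = labeling_config()) {
  stopifnot(is.matrix(posterior))
  if (any(abs(rowSums(posterior) - 1) > 1e-6)) {
    stop_ca("posterior rows must sum to 1")
  }
  consistency <- rep_len(consistency, nrow(posterior))
  best <- max.col(posterior, ties.method = "first")
  pmax_post <- posterior[cbind(seq_len(nrow(posterior)), best)]
  lab <- colnames(posterior)[best]
  lab[pmax_post < config$min_posterior |
        consistency < config$min_consistency] <- "unassigned"
  stats::setNames(lab, rownames(posterior))
}

#' Fraction of unassigned cells
#'
#' @param labels character label vector.
#' @return `count("unassigned") / length(labels)`.
#' @export
unassigned_fraction <- function(labels) {
  if (length(labels) == 0) stop_ca("labels must be nonempty")
  mean(labels == "unassigned")
}
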