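#' Construct an electrode montage
#'
#' @param labels character vector of unique channel labels.
#' @param positions numeric matrix (one row per channel, columns x and y) of
#'   flat scalp coordinates within the unit head circle. If omitted the
#'   channels are placed evenly on an inner circle, which is sufficient when
#'   only labels matter.
#' @return a [ChannelMontage-class].
#' @examples
#' ChannelMontage(c("FCz", "CPz"), rbind(c(0, 0.25), c(0, -0.25)))
#' @export
ChannelMontage <- function(labels, positions = NULL) {
  labels <- as.character(labels)
  if (is.null(positions)) {
    ang <- seq(0, 2 * pi, length.out = length(labels) + 1L)[seq_along(labels)]
    positions <- cbind(0.7 * sin(ang), 0.7 * cos(ang))
  }
  positions <- as.matrix(positions)
  dimnames(positions) <- list(labels, c("x", "y"))
  new("ChannelMontage", labels = labels, positions = positions)
}

#' Standard 10-10 montages
#'
#' Returns one of the two montage tables shipped with the package: a
#' 61-channel set (250 Hz cohort layout) or a 48-channel subset (256 Hz
#' cohort layout), both with standard extended 10-10 labels and flat
#' head-circle coordinates.
#'
#' @param which `"61"` or `"48"`.
#' @return a [ChannelMontage-class].
#' @examples
#' standardMontage("48")
#' @export
standardMontage <- function(which = c("61", "48")) {
  which <- match.arg(which)
  f <- system.file("extdata", sprintf("montage_1010_%s.csv", which),
                   package = "fractalEEG", mustWork = TRUE)
  readMontage(f)
}

#' Read a montage from CSV
#'
#' The file must have columns `label`, `x`, `y`.
#'
#' @param path path to a CSV file.
#' @return a [ChannelMontage-class].
#' @export
readMontage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y")
  if (!all(need %in% names(df)))
    stop("montage file must have columns label, x, y", call. = FALSE)
  ChannelMontage(df$label, cbind(df$x, df$y))
}

#' Subset a montage
#'
#' @param x a [ChannelMontage-class].
#' @param labels channels to keep, in the requested order.
#' @return a [ChannelMontage-class] restricted to `labels`.
#' @export
subsetMontage <- function(x, labels) {
  stopifnot(is(x, "ChannelMontage"))
  bad <- setdiff(labels, x@labels)
  if (length(bad))
    stop(sprintf("unknown channel(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  idx <- match(labels, x@labels)
  ChannelMontage(x@labels[idx], x@positions[idx, , drop = FALSE])
}
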