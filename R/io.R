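## Delimited-text interfaces: symbol/count tables in, probability tables out.

#' Read a symbol-count table
#'
#' Two-column delimited text: symbol index (1..m) and nonnegative count.
#' Symbols absent from the file receive count zero; \code{m} defaults to the
#' largest symbol present.
#'
#' @param path File path.
#' @param m Alphabet size (optional; must be >= the largest symbol listed).
#' @param sep Field separator (default whitespace/tab via
#'   \code{read.table}).
#' @return A \code{"count_vector"}.
#' @export
read_counts_table <- function(path, m = NULL, sep = "") {
  tab <- utils::read.table(path, header = FALSE, sep = sep,
                           col.names = c("symbol", "count"))
  if (any(tab$symbol < 1 | tab$symbol != round(tab$symbol)))
    stop("symbols must be positive integers")
  mm <- if (is.null(m)) max(tab$symbol) else as.integer(m)
  if (mm < max(tab$symbol)) stop("m smaller than largest symbol in file")
  counts <- numeric(mm)
  counts[tab$symbol] <- counts[tab$symbol] + tab$count
  count_vector(counts)
}

#' Read raw one-column numeric samples
#' @param path File path (one value per line; multiple columns give a
#'   multivariate sample matrix).
#' @return Numeric matrix, one sample per row.
#' @export
read_samples_table <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Write a (symbol, probability) table
#' @param p A \code{"discrete_distribution"}.
#' @param path Output path (tab-separated).
#' @return \code{path}, invisibly.
#' @export
write_probability_table <- function(p, path) {
  stopifnot(inherits(p, "discrete_distribution"))
  utils::write.table(data.frame(symbol = seq_len(p$m), probability = p$probs),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
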