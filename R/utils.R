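#' @noRd
stop_input <- function(...) stop(sprintf(...), call. = FALSE)

#' Numerically stable log(sum(exp(x)))
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Write a data frame as TSV (no quoting, no row names)
#'
#' All tabular outputs of the toolkit share this dialect.
#'
#' @param df data frame
#' @param path output file path
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Used to compare a detected community structure against a planted one.
#' Labels may be any atomic vectors of equal length.
#'
#' @param a,b partition label vectors of equal length
#' @return ARI in [-1, 1]; 1 for identical partitions
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop_input("partitions differ in length")
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
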