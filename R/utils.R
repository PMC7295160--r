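#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom qnorm pnorm dnorm pt pf qchisq
#'   median quantile sd var lm model.matrix p.adjust fisher.test loess
#'   predict kmeans complete.cases setNames integrate ks.test aggregate
#' @importFrom utils head read.delim write.table
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp for a matrix
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == as.integer(x) && x >= 0

# check a SampleTable-like data.frame has required columns
check_sample_table <- function(sample_table,
                               cols = c("sample_id", "age_days", "period",
                                        "epoch", "sex", "stage")) {
  missing <- setdiff(cols, names(sample_table))
  if (length(missing))
    stopf("sample table is missing columns: %s",
          paste(missing, collapse = ", "))
  invisible(sample_table)
}

ancestry_pc_cols <- function(sample_table, n = 5L) {
  cols <- paste0("pc", seq_len(n))
  missing <- setdiff(cols, names(sample_table))
  if (length(missing))
    stopf("sample table is missing ancestry PC columns: %s",
          paste(missing, collapse = ", "))
  cols
}
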