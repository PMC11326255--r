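#' @import methods
#' @importFrom stats predict
#' @importFrom utils head modifyList
NULL

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Locale-independent character sort (C collation) so that vocabularies and
## persisted tables are byte-identical across platforms.
.radixSort <- function(x) sort(x, method = "radix")

.stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "metpairs_error")))
}

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    .stopf("metpairs_config_error",
           "'%s' must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

.readJSON <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

.readTSV <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

## Matthews correlation coefficient from confusion counts, in double
## precision; any zero factor in the denominator yields the defined value 0.
.mccValue <- function(tp, tn, fp, fn) {
  tp <- as.numeric(tp); tn <- as.numeric(tn)
  fp <- as.numeric(fp); fn <- as.numeric(fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom <= 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

## Column-wise max/min of the stored (non-zero) values of a dgCMatrix,
## without densifying. Returns -Inf/Inf for columns with no stored values.
.colMaxNZ <- function(X) {
  p <- X@p
  x <- X@x
  vapply(seq_len(ncol(X)), function(j) {
    i0 <- p[j] + 1L; i1 <- p[j + 1L]
    if (i1 < i0) -Inf else max(x[i0:i1])
  }, numeric(1))
}

.colMinNZ <- function(X) {
  p <- X@p
  x <- X@x
  vapply(seq_len(ncol(X)), function(j) {
    i0 <- p[j] + 1L; i1 <- p[j + 1L]
    if (i1 < i0) Inf else min(x[i0:i1])
  }, numeric(1))
}
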