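#' @keywords internal
"_PACKAGE"

#' @importFrom stats dnorm dt kmeans optimize pt qbeta quantile rgamma rnorm
#'   runif sd setNames uniroot p.adjust optim rt median
#' @importFrom utils combn head
#' @importFrom Rcpp evalCpp
#' @useDynLib depmex, .registration = TRUE
NULL

.datatable.aware <- TRUE

# Condition constructors -------------------------------------------------

dmx_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "depmex_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

dmx_degenerate_error <- function(msg) dmx_error(msg, "depmex_degenerate_error")
dmx_validation_error <- function(msg, rows = NULL) {
  dmx_error(msg, "depmex_validation_error", rows = rows)
}

# Seed handling ----------------------------------------------------------

# All stochastic entry points take an integer `seed`; sub-seeds for named
# stages are derived deterministically so stages can be re-run in isolation.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 31 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# Structured logging (one JSON line per event), silenced by default ------

dmx_log <- function(stage, ..., verbose = getOption("depmex.verbose", FALSE)) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = stderr())
  invisible(NULL)
}

# Atomic write: write to a temp file in the same directory, then rename.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) dmx_error(sprintf("could not write '%s'", path),
                                         "depmex_io_error")
  invisible(path)
}
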