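# Structured conditions so callers (and the CLI) can map error families to
# exit codes: ev_domain_error / ev_assay_error / ev_data_error -> 1,
# ev_config_error -> 2.

ev_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "ev_error"), call = call))
}

ev_domain_error <- function(msg) ev_stop("ev_domain_error", msg)
ev_assay_error  <- function(msg) ev_stop("ev_assay_error", msg)
ev_config_error <- function(msg) ev_stop("ev_config_error", msg)
ev_data_error   <- function(msg) ev_stop("ev_data_error", msg)

check_numeric <- function(x, name, positive = FALSE, nonnegative = FALSE,
                          finite = TRUE) {
  if (!is.numeric(x) || length(x) == 0L)
    ev_domain_error(sprintf("'%s' must be a non-empty numeric vector", name))
  if (anyNA(x))
    ev_domain_error(sprintf("'%s' contains missing values", name))
  if (finite && any(!is.finite(x)))
    ev_domain_error(sprintf("'%s' contains non-finite values", name))
  if (positive && any(x <= 0))
    ev_domain_error(sprintf("'%s' must be strictly positive", name))
  if (nonnegative && any(x < 0))
    ev_domain_error(sprintf("'%s' must be nonnegative", name))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
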