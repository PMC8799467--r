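# Internal helpers: validation and classed error conditions.
#
# All user-facing errors carry a subclass of the form "panelkappa_error_<kind>"
# so callers (and the test suite) can match on the failure mode rather than on
# message text.

abort_pk <- function(kind, message, ...) {
  rlang::abort(message, class = paste0("panelkappa_error_", kind), ...)
}

#' @noRd
grade_levels <- function() 0:5

# Check a grade vector: integers in 0..5, NA allowed only if `allow_na`.
check_grades <- function(x, arg = "grades", allow_na = FALSE) {
  if (is.logical(x) && all(is.na(x))) x <- as.integer(x)
  if (!is.numeric(x)) {
    abort_pk("invalid_grade", sprintf("`%s` must be numeric grade labels (0-5).", arg))
  }
  bad_na <- is.na(x)
  if (!allow_na && any(bad_na)) {
    abort_pk("invalid_grade", sprintf("`%s` contains missing values.", arg))
  }
  xx <- x[!bad_na]
  if (length(xx) > 0 && (any(xx != floor(xx)) || any(xx < 0) || any(xx > 5))) {
    abort_pk(
      "invalid_grade",
      sprintf("`%s` must contain integer ISUP grade labels in 0-5 (0 = benign).", arg)
    )
  }
  invisible(as.integer(x))
}

check_finite <- function(x, arg = "values", kind = "invalid_metric") {
  if (length(x) == 0) {
    abort_pk("empty_input", sprintf("`%s` is empty.", arg))
  }
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort_pk(kind, sprintf("`%s` must be finite numeric values.", arg))
  }
  invisible(as.double(x))
}

# Derive a reproducible child seed from a user seed; stays below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}
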