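# internal validation helpers shared across modules

check_columns <- function(data, required, what = "input table",
                          call = rlang::caller_env()) {
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing_cols) > 1) "s" else "",
        paste(missing_cols, collapse = ", ")
      ),
      class = "holophos_schema_error",
      call = call
    )
  }
  invisible(data)
}

check_positive <- function(x, name, strict = TRUE,
                           call = rlang::caller_env()) {
  bad <- if (strict) !is.finite(x) | x <= 0 else !is.finite(x) | x < 0
  if (any(bad)) {
    abort(
      sprintf(
        "`%s` must be %s and finite (offending value%s: %s)",
        name, if (strict) "> 0" else ">= 0",
        if (sum(bad) > 1) "s" else "",
        paste(utils::head(x[bad], 5), collapse = ", ")
      ),
      class = "holophos_input_error",
      call = call
    )
  }
  invisible(x)
}

# summary.lm warns on zero-residual fits; noiseless fixtures are a
# supported input here, so that warning is muffled.
quiet_summary <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# fraction in (0, 1]
check_fraction <- function(x, name, call = rlang::caller_env()) {
  if (!is.numeric(x) || any(!is.finite(x) | x <= 0 | x > 1)) {
    abort(sprintf("`%s` must lie in (0, 1]", name),
          class = "holophos_input_error", call = call)
  }
  invisible(x)
}
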