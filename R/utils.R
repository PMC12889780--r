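# internal helpers shared across modules

# signalled conditions carry a subclass so callers can branch on the
# specific validation failure (tests rely on these names)
azfcError <- function(subclass, message, call = sys.call(-1)) {
  stop(structure(
    class = c(subclass, "azfc_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

# rolling polynomial hash over a canonical serialization; only used to bind
# a signature catalog to the definition set it was validated against
contentChecksum <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x, digits.d = 12)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  m <- 2147483647  # 2^31 - 1; 31 * m < 2^53 so double arithmetic is exact
  for (b in bytes) h <- (h * 31 + b) %% m
  sprintf("%08x", h)
}

# nearest integer, exact halves away from zero, floored at 0
roundHalfAway <- function(x) {
  pmax(0L, as.integer(sign(x) * floor(abs(x) + 0.5)))
}

stopifnotNamed <- function(x, what) {
  if (is.null(names(x)) || any(!nzchar(names(x))) || anyDuplicated(names(x))) {
    azfcError("azfc_key_mismatch",
              sprintf("%s must have unique non-empty names", what))
  }
}

# '--key value' argv parser for the pipeline entry point; bare '--flag'
# followed by another option (or end of argv) becomes TRUE
parseArgv <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      azfcError("azfc_cli_error", sprintf("unexpected argument '%s'", a))
    }
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  out
}

outputHeader <- function(seed = NA, extra = character()) {
  c(sprintf("# azfcCaller %s", as.character(utils::packageVersion("azfcCaller"))),
    sprintf("# seed=%s", as.character(seed)),
    if (length(extra)) paste0("# ", extra))
}
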