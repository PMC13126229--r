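#' @importFrom rlang %||% abort warn inform
#' @importFrom stats runif rbinom
#' @importFrom utils URLencode URLdecode modifyList head tail
NULL

# Registers supported end-to-end.
REGISTERS <- c("CTGOV", "CTIS", "EUCTR", "ISRCTN")

# EEA country codes (EU27 + IS, LI, NO); EUCTR site counting is restricted to
# these, mirroring the register's lack of site data for non-EEA countries.
EEA_COUNTRIES <- c(
  "AT", "BE", "BG", "HR", "CY", "CZ", "DK", "EE", "FI", "FR", "DE", "GR",
  "HU", "IE", "IT", "LV", "LT", "LU", "MT", "NL", "PL", "PT", "RO", "SK",
  "SI", "ES", "SE", "IS", "LI", "NO"
)

round_half_up <- function(x) floor(x + 0.5)

is_missing_scalar <- function(x) {
  is.null(x) || length(x) == 0 ||
    (length(x) == 1 && (is.na(x) || identical(as.character(x), "")))
}

# Register null literals normalised to NA before tabulation/merging.
NULL_LITERALS <- c("", "NULL", "NA", "N/A", "null")

normalize_missing <- function(x) {
  if (is.null(x)) return(NA_character_)
  x <- as.character(x)
  x[x %in% NULL_LITERALS] <- NA_character_
  x
}

assert_that <- function(ok, msg, class = "regharvest_error") {
  if (!ok) abort(msg, class = c(class, "regharvest_error"))
  invisible(TRUE)
}

`%theni%` <- function(x, y) if (is_missing_scalar(x)) y else x

is_iso_date <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}$", as.character(x))
}

as_date_safe <- function(x) {
  out <- suppressWarnings(as.Date(as.character(x), format = "%Y-%m-%d"))
  out
}

# Config (grammar + vocabulary tables) is shipped as YAML and cached per session.
the <- new.env(parent = emptyenv())

regharvest_config <- function(which = c("grammars", "vocabularies")) {
  which <- match.arg(which)
  key <- paste0("cfg_", which)
  if (is.null(the[[key]])) {
    path <- system.file("extdata", paste0(which, ".yaml"), package = "regharvest")
    if (!nzchar(path)) {
      # during development (pkgload) inst/ is mapped directly
      path <- file.path("inst", "extdata", paste0(which, ".yaml"))
    }
    the[[key]] <- yaml::read_yaml(path)
  }
  the[[key]]
}
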