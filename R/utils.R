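# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# The four phosphate regimes of the graft experiment, in fixed order:
# full Pi 7 d; no Pi 3 d; no Pi 7 d; no Pi 7 d then resupply 2 d.
PI_CONDITIONS <- c("FP7D", "NP3D", "NP7D", "NP7DRP2D")

# Condition groups used for specificity classification: mobility seen only
# under -Pi is "Pi starvation induced" (PSI), only under +Pi is
# "Pi starvation decreased" (PSD).
MINUS_PI <- c("NP3D", "NP7D")
PLUS_PI <- c("FP7D", "NP7DRP2D")

DNA_BASES <- c("A", "C", "G", "T")

#' Phosphate treatment conditions
#'
#' Returns the four phosphate regimes the graft design uses, in canonical
#' order: `FP7D` (Pi-sufficient control), `NP3D` (3 d Pi starvation), `NP7D`
#' (7 d Pi starvation) and `NP7DRP2D` (7 d starvation, 2 d resupply).
#'
#' @return Character vector of length four.
#' @export
pi_conditions <- function() PI_CONDITIONS

# Evaluate `code` under a fixed RNG seed without clobbering the caller's
# RNG state.
with_seed <- function(seed, code) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_param("`", name, "` must be TRUE or FALSE")
  }
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop_param("`", name, "` must be a single integer >= ", min)
  }
  as.integer(x)
}

check_prob <- function(x, name, lower = 0, upper = 1,
                       lower_open = FALSE, upper_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lower_open) x > lower else x >= lower) &&
    (if (upper_open) x < upper else x <= upper)
  if (!ok) {
    stop_param("`", name, "` must be in ",
               if (lower_open) "(" else "[", lower, ", ", upper,
               if (upper_open) ")" else "]")
  }
  as.numeric(x)
}

# Reverse complement of a DNA/RNA character string, via Biostrings.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Uppercase and map U -> T so sequences can be compared on the DNA alphabet.
dna_norm <- function(seq) chartr("u", "U", toupper(seq)) |>
  (\(s) chartr("U", "T", s))()

# Uppercase and map T -> U (RNA alphabet).
rna_norm <- function(seq) chartr("t", "T", toupper(seq)) |>
  (\(s) chartr("T", "U", s))()

check_nt <- function(seq, name, alphabet = c(DNA_BASES, "U")) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), alphabet)
  if (length(bad)) {
    stop_param("`", name, "` contains non-nucleotide characters: ",
               paste(bad, collapse = ", "))
  }
  invisible(seq)
}
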