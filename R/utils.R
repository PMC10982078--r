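# Internal helpers shared across modules.

# Run `expr` under a fixed Mersenne-Twister seed, restoring the caller's
# RNG state afterwards so library code never perturbs a user's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

#' Reverse complement of a nucleotide string
#'
#' Plain-character reverse complement over the alphabet `ACGTN`
#' (case-insensitive; output is uppercase). `N` maps to `N`.
#'
#' @param x a single nucleotide string.
#' @return the reverse-complemented string.
#' @examples
#' reverse_complement("ATGCN")
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  comp <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# Round half away from zero (MEGA-style table rendering); base round()
# rounds half to even.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a fractional distance as a percentage string
#'
#' Distances are stored as fractions in `[0, 1]`; published distance
#' tables print percentages with one decimal, rounding half away from
#' zero. This helper applies that rendering at the reporting layer only.
#'
#' @param x numeric vector of fractions.
#' @return character vector like `"22.4%"`; `NA` stays `NA`.
#' @export
format_pct <- function(x) {
  out <- ifelse(is.na(x), NA_character_,
                paste0(formatC(round_half_up(100 * x, 1), format = "f",
                               digits = 1), "%"))
  out
}

# Validate a 0/1 presence matrix with sample rownames / transcript colnames.
check_presence_matrix <- function(m) {
  if (!is.matrix(m)) stop("presence matrix must be a matrix", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("presence matrix needs sample rownames and transcript colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate sample IDs", call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("duplicate transcript IDs", call. = FALSE)
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    stop("presence matrix cells must all be 0 or 1", call. = FALSE)
  }
  invisible(m)
}
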