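# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Random i.i.d. DNA with a given GC fraction.
random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

stopifnot_scalar_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

#' Parse a chromosome label with an optional arm suffix
#'
#' Splits labels such as `"1p"`, `"8q"` or `"6"` into an integer chromosome
#' number and an arm. An arm-less label means "arm unknown", not "whole
#' chromosome"; the two notations can be mixed freely in one table.
#'
#' @param x Character vector of labels (e.g. `c("1p", "6", "8q")`).
#' @return A data.frame with columns `chromosome` (integer) and `arm`
#'   (`"p"`, `"q"` or `NA`).
#' @examples
#' parse_chrom_label(c("1p", "6", "22"))
#' @export
parse_chrom_label <- function(x) {
  x <- trimws(as.character(x))
  arm <- ifelse(grepl("[pq]$", x), substring(x, nchar(x)), NA_character_)
  num <- suppressWarnings(as.integer(sub("[pq]$", "", x)))
  if (anyNA(num))
    stop("unparseable chromosome label(s): ",
         paste(unique(x[is.na(num)]), collapse = ", "), call. = FALSE)
  data.frame(chromosome = num, arm = arm, stringsAsFactors = FALSE)
}
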