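# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

#' Atomic number lookup
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return integer vector of atomic numbers.
#' @export
element_number <- function(element) {
  tab <- c(H = 1, C = 6, N = 7, O = 8, F = 9, NA. = 11, MG = 12, P = 15,
           S = 16, CL = 17, K = 19, CA = 20, MN = 25, FE = 26, ZN = 30,
           BR = 35, I = 53)
  key <- toupper(trimws(element))
  key[key == "NA"] <- "NA."
  z <- tab[key]
  if (anyNA(z))
    stop("element_number: unknown element(s): ",
         paste(unique(element[is.na(z)]), collapse = ", "), call. = FALSE)
  as.integer(z)
}
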