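#' @useDynLib phosnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor median p.adjust pnorm pt rbinom rnorm runif sd var
#' @importFrom utils read.delim write.csv head
NULL

# Run expr with a local RNG seed, restoring the caller's RNG state afterwards.
# All stochastic functions in the package funnel their randomness through this
# helper so that a seed argument fully determines their output and no global
# state leaks.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a base seed and a stage offset, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(offset) * 12289) %% 2147483647)
}

#' Build a phosphosite identifier
#'
#' Site identifiers follow the \code{"ACC;S473"} convention used by
#' site-centric signature databases: protein accession, then residue letter and
#' 1-based protein position, separated by a semicolon.
#'
#' @param protein Protein accession or gene symbol.
#' @param residue Single residue letter (e.g. \code{"S"}).
#' @param position 1-based position within the protein sequence.
#' @return Character vector of site ids.
#' @examples
#' site_id("P31749", "S", 473)
#' @export
site_id <- function(protein, residue, position) {
  paste0(protein, ";", residue, position)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
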