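#' Find primer binding sites on a template
#'
#' Scans both strands of an unaligned template at every offset. A site
#' qualifies when the number of IUPAC-incompatible positions is at most
#' `max_mm` AND the primer's 3'-terminal `three_prime_exact` bases are all
#' compatible (extension initiates at the 3' end, so mismatches there
#' abort amplification). Degenerate primer positions match any base in
#' their IUPAC set.
#'
#' `start` is the leftmost plus-strand coordinate of the primer footprint
#' (0-based, half-open `[start, start + nchar(primer))`), on both strands.
#' On the plus strand the primer's 3' end is the rightmost footprint base;
#' on the minus strand it is the leftmost.
#'
#' @param primer primer sequence 5'->3' (IUPAC codes allowed).
#' @param template an unaligned template sequence (plus strand).
#' @param max_mm maximum tolerated mismatches outside the 3' clamp.
#' @param three_prime_exact number of 3'-terminal bases that must match.
#' @param all if `TRUE` return every qualifying site; otherwise only the
#'   best one (fewest mismatches; ties broken by plus strand first, then
#'   leftmost start).
#' @return a `data.frame` with columns `strand`, `start`, `mismatches`
#'   (zero rows if no site qualifies).
#' @export
binds <- function(primer, template, max_mm = 2L, three_prime_exact = 3L,
                  all = FALSE) {
  stopifnot(is.character(primer), length(primer) == 1L,
            is.character(template), length(template) == 1L)
  sites <- cpp_scan_sites(primer, template, as.integer(max_mm),
                          as.integer(three_prime_exact))
  if (nrow(sites) == 0L || all) {
    return(sites[order(sites$start, sites$strand), , drop = FALSE])
  }
  o <- order(sites$mismatches, sites$strand != "+", sites$start)
  sites[o[1L], , drop = FALSE]
}
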