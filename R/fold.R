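#' Secondary-structure folding energy of a sequence
#'
#' The default backend maximizes nested Watson-Crick + GU base pairs with a
#' minimum hairpin-loop size (Nussinov dynamic program); its energy is minus
#' the maximal pair count, so more negative means more structured. The
#' normalized value (NMFE) divides by sequence length in nt. A thermodynamic
#' backend (`"rnafold"`, requires the ViennaRNA `RNAfold` binary on the
#' PATH) honours the same contract: `energy <= 0`, `nmfe = energy / length`.
#' Energies from the two backends are on different scales (pair counts vs
#' kcal/mol) and are comparable only within one backend.
#'
#' @param sequence A single DNA/RNA string (A/C/G/T/U/N).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair
#'   (default 3); ignored by the thermodynamic backend.
#' @param backend `"nussinov"` (default) or `"rnafold"`.
#' @return A list with `energy` (<= 0) and `nmfe` (`energy / length`).
#' @examples
#' nussinov_mfe("GGGAAACCC") # energy -3, nmfe -1/3
#' @export
nussinov_mfe <- function(sequence, min_loop = 3L, backend = "nussinov") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) abort("empty sequence")
  if (!grepl("^[ACGTUN]+$", sequence)) {
    abort("sequence contains characters outside A/C/G/T/U/N")
  }
  n <- nchar(sequence)
  backend <- match.arg(backend, c("nussinov", "rnafold"))
  energy <- if (backend == "nussinov") {
    -nussinov_pairs_cpp(chartr("U", "T", sequence), as.integer(min_loop))
  } else {
    rnafold_energy(sequence)
  }
  list(energy = energy, nmfe = energy / n)
}

# thermodynamic plug-in backend via the RNAfold CLI
rnafold_energy <- function(sequence) {
  bin <- Sys.which("RNAfold")
  if (!nzchar(bin)) abort("RNAfold binary not found on PATH")
  out <- system2(bin, args = "--noPS", input = chartr("T", "U", sequence),
                 stdout = TRUE)
  last <- out[length(out)]
  e <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", last))
  if (is.na(e)) abort("could not parse RNAfold output")
  min(e, 0)
}

#' Normalized folding energies for a set of sequences
#'
#' @param sequences Character vector of sequences.
#' @param min_loop Minimum hairpin-loop size.
#' @param backend Folding backend, see [nussinov_mfe()].
#' @return Tibble with `energy` and `nmfe` per sequence.
#' @export
fold_energies <- function(sequences, min_loop = 3L, backend = "nussinov") {
  res <- purrr::map(sequences, nussinov_mfe, min_loop = min_loop,
                    backend = backend)
  tibble(
    energy = vapply(res, `[[`, numeric(1), "energy"),
    nmfe = vapply(res, `[[`, numeric(1), "nmfe")
  )
}
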