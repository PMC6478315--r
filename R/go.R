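#' Go-model parameters
#'
#' Parameters of the 12-10 native-contact potential acting between the alpha
#' carbons of coarse-grained residues.  Defaults are the production values:
#' well depth 3.0 kcal/mol, hard-core radius 1.7 A, native-contact cutoff 8 A.
#'
#' @param epsilon Well depth in kcal/mol (> 0).
#' @param r_hc Hard-core radius in Angstrom (> 0), used by the repulsive
#'   nonnative term.
#' @param native_cutoff Reference alpha-carbon distance below which a residue
#'   pair is a native contact, Angstrom.
#' @return An object of class `"go_parameters"`.
#' @export
go_parameters <- function(epsilon = 3.0, r_hc = 1.7, native_cutoff = 8) {
  stopifnot(epsilon > 0, r_hc > 0, native_cutoff > 0)
  structure(list(epsilon = epsilon, r_hc = r_hc,
                 native_cutoff = native_cutoff),
            class = "go_parameters")
}

#' Build the native-contact list from a reference structure
#'
#' One contact is recorded for every coarse-coarse residue pair whose
#' reference alpha-carbon distance is below the native cutoff and whose
#' sequence separation is at least `min_separation` (closer pairs are covered
#' by the backbone bonded terms).  All other coarse-coarse pairs with the
#' same separation constraint are treated as nonnative by the energy model.
#'
#' @param reference An `mrmc_system` whose `xyz` holds the native
#'   (reference) configuration and whose residues carry region labels.
#' @param params A [go_parameters()] object.
#' @param min_separation Minimum sequence separation for Go pairs (default 3).
#' @return data.frame with columns `i`, `j` (residue indices, `i < j`) and
#'   `r0` (native alpha-carbon distance, A).
#' @export
build_native_contacts <- function(reference, params = go_parameters(),
                                  min_separation = 3) {
  res <- reference$residues
  coarse <- which(res$region == "coarse")
  if (length(coarse) < 2)
    return(data.frame(i = integer(), j = integer(), r0 = numeric()))
  ca <- res$calpha[coarse]
  if (any(is.na(ca)))
    stop("validation error: missing alpha carbon for coarse residue ",
         coarse[which(is.na(ca))[1]])
  D <- dist_cross(reference$xyz[ca, , drop = FALSE],
                  reference$xyz[ca, , drop = FALSE])
  out <- list()
  nc <- length(coarse)
  for (a in seq_len(nc - 1)) {
    for (b in (a + 1):nc) {
      if (abs(coarse[b] - coarse[a]) < min_separation) next
      if (D[a, b] < params$native_cutoff)
        out[[length(out) + 1L]] <- c(coarse[a], coarse[b], D[a, b])
    }
  }
  if (length(out) == 0)
    return(data.frame(i = integer(), j = integer(), r0 = numeric()))
  m <- do.call(rbind, out)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]), r0 = m[, 3])
}

#' 12-10 Go pair energy
#'
#' Native pairs: `epsilon * (5 (r0/r)^12 - 6 (r0/r)^10)`, a well of depth
#' `epsilon` with its minimum exactly at `r = r0`.  Nonnative pairs:
#' `5 * epsilon * (r_hc/r)^12`, purely repulsive.
#'
#' @param r Alpha-carbon distance(s), A (> 0); vectorised.
#' @param is_native Logical: native or nonnative branch.
#' @param r0 Native distance (required iff `is_native`).
#' @param params A [go_parameters()] object.
#' @return Energy in kcal/mol, same length as `r`.
#' @export
go_pair_energy <- function(r, is_native, r0 = NULL,
                           params = go_parameters()) {
  if (any(r <= 0)) stop("domain error: r must be positive")
  if (is_native) {
    if (is.null(r0)) stop("domain error: native pair requires r0")
    x <- r0 / r
    params$epsilon * (5 * x^12 - 6 * x^10)
  } else {
    5 * params$epsilon * (params$r_hc / r)^12
  }
}

#' Serialize a native-contact list to tabular text
#'
#' Writes one `i j r0` row per contact for reproducibility.
#'
#' @param contacts data.frame from [build_native_contacts()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_native_contacts <- function(contacts, path) {
  utils::write.table(contacts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a native-contact list written by [write_native_contacts()]
#' @param path Input path.
#' @return data.frame with columns `i`, `j`, `r0`.
#' @export
read_native_contacts <- function(path) {
  utils::read.table(path, header = TRUE)
}
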