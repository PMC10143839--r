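#' The 60-name MOE-type descriptor registry
#'
#' Seven families of 2D physicochemical descriptors that partition each
#' molecule's approximate van der Waals surface area (VSA) by an atomic
#' property, plus two totals:
#' `slogPVSA0..11` (Crippen logP bins), `MRVSA0..9` (Crippen molar
#' refractivity bins), `PEOEVSA0..13` (Gasteiger partial-charge bins),
#' `EstateVSA0..10` (VSA summed in E-state index bins), `VSAEstate0..10`
#' (E-state indices summed in VSA bins), `LabuteASA` (total approximate
#' surface area), and `MTPSA` (Ertl topological polar surface area).
#' Fixed order; 60 names.
#'
#' @return Character vector of the 60 descriptor names, in registry order.
#' @export
moe_descriptor_registry <- function() {
  c(paste0("slogPVSA", 0:11),
    paste0("MRVSA", 0:9),
    paste0("PEOEVSA", 0:13),
    paste0("EstateVSA", 0:10),
    paste0("VSAEstate", 0:10),
    "LabuteASA", "MTPSA")
}

#' Compute MOE-type descriptors for molecules
#'
#' Computes the 60-descriptor vector for each molecule. Atomic-contribution
#' computation (Gasteiger charges, Crippen logP/MR contributions, E-state
#' indices, Labute surface area, Ertl TPSA) is delegated to RDKit; this
#' function assembles the registry-ordered vectors. Values are cached per
#' SMILES, so repeated calls over the same molecules are free.
#'
#' @param x a [compound_set] or a character vector of valid SMILES.
#' @param id identifiers for the output rows; defaults to `x$id` for a
#'   compound set, else the SMILES themselves.
#' @return Tibble with column `id` plus the 60 named descriptor columns,
#'   one row per molecule.
#' @export
compute_moe_descriptors <- function(x, id = NULL) {
  if (inherits(x, "compound_set")) {
    id <- id %||% x$id
    smiles <- ifelse(is.na(x$canonical_smiles), x$smiles, x$canonical_smiles)
  } else {
    .assert(is.character(x), "x must be a compound_set or SMILES vector")
    smiles <- x
    id <- id %||% smiles
  }
  reg <- moe_descriptor_registry()
  keys <- paste0("d|", smiles)
  memo <- .memo_get("descriptors", keys)
  todo <- which(!memo$hit)
  if (length(todo)) {
    res <- .rdkit_call("desc", smiles[todo])
    for (i in seq_along(todo)) {
      if (nzchar(res$error[[i]])) .stopf("%s", res$error[[i]])
      v <- as.numeric(res[i, reg])
      if (any(!is.finite(v))) {
        .stopf("non-finite descriptor %s for %s",
               reg[which(!is.finite(v))[1]], smiles[todo[i]])
      }
      memo$env[[keys[todo[i]]]] <- v
    }
  }
  m <- t(vapply(keys, function(k) memo$env[[k]], numeric(length(reg)),
                USE.NAMES = FALSE))
  colnames(m) <- reg
  out <- tibble::as_tibble(m)
  out <- tibble::add_column(out, id = as.character(id), .before = 1)
  out
}

#' Lorentz-Lorenz molar refractivity
#'
#' `MR = ((n^2 - 1) / (n^2 + 2)) * (MW / d)`, linking a bulk substance's
#' refractive index `n` (dimensionless), molecular weight `MW` (g/mol), and
#' density `d` (g/cm^3). MR (cm^3/mol) tracks molecular polarizability. This
#' is the bulk-property route to MR; the per-atom `MRVSA*` descriptor bins
#' instead come from Crippen atomic contributions, which need only the
#' structure.
#'
#' @param n refractive index, `>= 1`.
#' @param mw molecular weight in g/mol, `> 0`.
#' @param d density in g/cm^3, `> 0`.
#' @return Molar refractivity in cm^3/mol. Vectorized.
#' @examples
#' molar_refractivity(n = 1.333, mw = 18.015, d = 0.997)  # liquid water
#' @export
molar_refractivity <- function(n, mw, d) {
  .assert(all(is.finite(n)) && all(n >= 1), "refractive index must be >= 1")
  .assert(all(is.finite(mw)) && all(mw > 0), "molecular weight must be > 0")
  .assert(all(is.finite(d)) && all(d > 0), "density must be > 0")
  ((n^2 - 1) / (n^2 + 2)) * (mw / d)
}
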