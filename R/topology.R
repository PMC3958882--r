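#' @title Per-atom topology table
#'
#' @description
#' A `topology` is a data frame with one row per atom carrying the physical
#' parameters needed by the energy and interaction analyses: mass, partial
#' charge, Lennard-Jones parameters (`lj_rmin_half`, `lj_epsilon`), intrinsic
#' Born radius and HCT screening factor, plus residue/chain bookkeeping and a
#' polarity class used for hydrophobic-contact detection.
#'
#' Required columns: `atom_id`, `name`, `element`, `residue_index`,
#' `residue_name`, `chain_id`, `mass`, `charge`, `lj_rmin_half`,
#' `lj_epsilon`, `born_radius`, `screen_factor`, `polarity_class`.
#'
#' Invariants enforced: masses and Born radii strictly positive; LJ epsilon
#' non-negative; `atom_id` strictly increasing; each `residue_index` belongs
#' to exactly one `chain_id`; `polarity_class` is `"polar"` or `"nonpolar"`.
#'
#' @param df data frame with the columns above.
#' @return `df` with class `topology` prepended, after validation.
#' @export
topology <- function(df) {
  required <- c("atom_id", "name", "element", "residue_index", "residue_name",
                "chain_id", "mass", "charge", "lj_rmin_half", "lj_epsilon",
                "born_radius", "screen_factor", "polarity_class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("topology: missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)

  bad_mass <- df$atom_id[!(is.finite(df$mass) & df$mass > 0)]
  if (length(bad_mass) > 0L) {
    stop("topology: non-positive mass for atom_id(s): ",
         paste(bad_mass, collapse = ", "))
  }
  bad_radius <- df$atom_id[!(is.finite(df$born_radius) & df$born_radius > 0)]
  if (length(bad_radius) > 0L) {
    stop("topology: non-positive born_radius for atom_id(s): ",
         paste(bad_radius, collapse = ", "))
  }
  if (any(df$lj_epsilon < 0)) {
    stop("topology: lj_epsilon must be >= 0")
  }
  if (any(diff(df$atom_id) <= 0)) {
    stop("topology: atom_id must be strictly increasing")
  }
  chain_per_res <- tapply(df$chain_id, df$residue_index,
                          function(x) length(unique(x)))
  if (any(chain_per_res > 1L)) {
    bad <- names(chain_per_res)[chain_per_res > 1L]
    stop("topology: residue_index in more than one chain: ",
         paste(bad, collapse = ", "))
  }
  if (!all(df$polarity_class %in% c("polar", "nonpolar"))) {
    stop("topology: polarity_class must be 'polar' or 'nonpolar'")
  }
  class(df) <- c("topology", "data.frame")
  df
}

#' Read a topology table
#'
#' Reads the package's tab-separated per-atom parameter table (one row per
#' atom, header naming every topology column) and validates all invariants.
#'
#' @param path path to a TSV file.
#' @return a [topology] data frame.
#' @export
read_topology_table <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  topology(df)
}

#' Write a topology table
#'
#' @param top a [topology].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_topology_table <- function(top, path) {
  utils::write.table(as.data.frame(top), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, chains: %s\n",
              nrow(x), length(unique(x$residue_index)),
              paste(unique(x$chain_id), collapse = ", ")))
  invisible(x)
}

# internal: check that a topology and a trajectory agree on atom count
check_topology_trajectory <- function(top, traj) {
  if (nrow(top) != traj$n_atoms) {
    stop(sprintf("topology has %d atoms but trajectory has %d",
                 nrow(top), traj$n_atoms))
  }
  invisible(TRUE)
}
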