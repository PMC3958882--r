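#' @title Helix annotation map
#'
#' @description
#' A `helix_map` names the helix segments of each monomer. Segment names are
#' single letters A..I (the conventional labels for the nine helices of a
#' 14-3-3 monomer, A-D forming the dimerization base, E-F the hinge and G-I
#' the mobile top); each maps to an inclusive 1-based residue range. Both
#' chains must define the same segment names, and ranges may not overlap
#' within a chain.
#'
#' @param chains named list (one element per chain, e.g. `A`, `B`); each a
#'   named list of length-2 integer vectors `c(first_residue, last_residue)`.
#' @param top optional [topology]; when given, ranges are checked to lie
#'   within each chain's residue span.
#' @return an object of class `helix_map`.
#' @export
helix_map <- function(chains, top = NULL) {
  if (length(chains) == 0L) stop("helix_map: no chains given")
  seg_names <- lapply(chains, names)
  for (ch in names(chains)) {
    segs <- chains[[ch]]
    if (is.null(names(segs)) || any(names(segs) == "")) {
      stop("helix_map: unnamed segment in chain ", ch)
    }
    bad <- setdiff(names(segs), LETTERS[1:9])
    if (length(bad) > 0L) {
      stop("helix_map: segment name(s) outside A-I in chain ", ch, ": ",
           paste(bad, collapse = ", "))
    }
    for (s in names(segs)) {
      rng <- segs[[s]]
      if (length(rng) != 2L || anyNA(rng) || rng[1] > rng[2]) {
        stop("helix_map: invalid range for segment ", s, " in chain ", ch)
      }
      chains[[ch]][[s]] <- as.integer(rng)
    }
    # overlap check
    ord <- order(vapply(segs, function(r) r[1], numeric(1)))
    sorted <- segs[ord]
    if (length(sorted) > 1L) {
      for (k in 2:length(sorted)) {
        if (sorted[[k]][1] <= sorted[[k - 1]][2]) {
          stop("helix_map: overlapping ranges in chain ", ch, ": ",
               names(sorted)[k - 1], " and ", names(sorted)[k])
        }
      }
    }
  }
  if (length(unique(lapply(seg_names, sort))) != 1L) {
    stop("helix_map: chains define different segment names")
  }
  if (!is.null(top)) {
    for (ch in names(chains)) {
      res_span <- range(top$residue_index[top$chain_id == ch])
      if (length(res_span) == 0L || !is.finite(res_span[1])) {
        stop("helix_map: chain ", ch, " not present in topology")
      }
      for (s in names(chains[[ch]])) {
        rng <- chains[[ch]][[s]]
        if (rng[1] < res_span[1] || rng[2] > res_span[2]) {
          stop("helix_map: segment ", s, " in chain ", ch,
               " outside the chain's residue span")
        }
      }
    }
  }
  structure(list(chains = chains), class = "helix_map")
}

#' Read a helix map from a YAML config
#'
#' Expected layout:
#' ```yaml
#' chains:
#'   A: {A: [1, 10], B: [12, 20]}
#'   B: {A: [31, 40], B: [42, 50]}
#' ```
#'
#' @param path YAML file path.
#' @param top optional [topology] for span validation.
#' @return a [helix_map].
#' @export
read_helix_map <- function(path, top = NULL) {
  if (!file.exists(path)) stop("helix map file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$chains)) stop("helix map config must have a 'chains' key")
  helix_map(cfg$chains, top = top)
}

#' Write a helix map YAML config
#'
#' @param hmap a [helix_map].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_helix_map <- function(hmap, path) {
  yaml::write_yaml(list(chains = hmap$chains), path)
  invisible(path)
}

#' @export
print.helix_map <- function(x, ...) {
  for (ch in names(x$chains)) {
    segs <- x$chains[[ch]]
    cat("chain ", ch, ": ",
        paste(sprintf("%s:%d-%d", names(segs),
                      vapply(segs, `[`, integer(1), 1L),
                      vapply(segs, `[`, integer(1), 2L)), collapse = "  "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Atom indices of helix segments
#'
#' @param hmap a [helix_map].
#' @param top a [topology].
#' @param chain chain id.
#' @param segments character vector of segment names (subset of those in the
#'   map).
#' @return integer vector of row indices into `top`.
#' @export
helix_atoms <- function(hmap, top, chain, segments) {
  if (!chain %in% names(hmap$chains)) {
    stop("helix_atoms: chain ", chain, " not in helix map")
  }
  segs <- hmap$chains[[chain]]
  missing <- setdiff(segments, names(segs))
  if (length(missing) > 0L) {
    stop("helix_atoms: segment(s) not defined: ",
         paste(missing, collapse = ", "))
  }
  idx <- integer(0)
  for (s in segments) {
    rng <- segs[[s]]
    idx <- c(idx, which(top$chain_id == chain &
                          top$residue_index >= rng[1] &
                          top$residue_index <= rng[2]))
  }
  sort(unique(idx))
}
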