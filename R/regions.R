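#' Residue-range regions and glycan annotations
#'
#' Regions are named sets of inclusive author-numbered residue ranges (the
#' field's convention: the N-terminal autoinhibitory module is residues
#' 1238-1271, the C-terminal one 1459-1493, the A1 anchor 1290-1430, the
#' receptor 1-265, the whole mechanomodule 764-1873). All interval logic is
#' inclusive on both ends.
#'
#' @name regions
NULL

#' Define a residue-range region
#'
#' @param name region label.
#' @param ranges numeric vector `c(start, end)` or list of such pairs;
#'   inclusive on both ends, non-overlapping.
#' @param chain chain identifier, or `NA` for any chain.
#' @param heavy_only restrict selections to heavy atoms (default `TRUE`).
#' @return a `region_spec`.
#' @export
region_spec <- function(name, ranges, chain = NA, heavy_only = TRUE) {
  if (!is.list(ranges)) ranges <- list(ranges)
  ranges <- lapply(ranges, function(r) {
    r <- as.numeric(r)
    if (length(r) != 2 || !all(is.finite(r))) stop("range must be (start, end)")
    if (r[1] > r[2]) stop("range start > end in region '", name, "'")
    r
  })
  if (length(ranges) > 1) {
    o <- order(vapply(ranges, `[`, 0, 1))
    ranges <- ranges[o]
    for (i in seq_len(length(ranges) - 1)) {
      if (ranges[[i]][2] >= ranges[[i + 1]][1]) {
        stop("overlapping ranges in region '", name, "'")
      }
    }
  }
  structure(list(name = name, chain = chain, ranges = ranges,
                 heavy_only = isTRUE(heavy_only)),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  rng <- paste(vapply(x$ranges, function(r) paste0(r[1], "-", r[2]),
                      character(1)), collapse = ", ")
  cat("<region_spec>", x$name, "chain",
      if (is.na(x$chain)) "*" else x$chain, ":", rng,
      if (x$heavy_only) "(heavy atoms)\n" else "(all atoms)\n")
  invisible(x)
}

#' Number of residue positions covered by a region
#'
#' Counts author-numbered positions in the inclusive ranges (e.g. the
#' mechanomodule span 764-1873 covers 1110 residues).
#' @param spec a `region_spec`.
#' @export
region_n_residues <- function(spec) {
  sum(vapply(spec$ranges, function(r) r[2] - r[1] + 1, 0))
}

#' Merge regions into one spec
#'
#' @param name name of the merged region.
#' @param ... `region_spec` objects with non-overlapping ranges and equal
#'   `chain`/`heavy_only`.
#' @export
merge_regions <- function(name, ...) {
  specs <- list(...)
  region_spec(name,
              ranges = unlist(lapply(specs, `[[`, "ranges"), recursive = FALSE),
              chain = specs[[1]]$chain,
              heavy_only = specs[[1]]$heavy_only)
}

#' Select atoms covered by a region
#'
#' Selection order follows structure order; with `heavy_only` the elements
#' H and D are excluded. An empty selection is allowed but raises a warning.
#'
#' @param structure a `vwf_structure`.
#' @param spec a `region_spec`.
#' @param quiet suppress the empty-selection warning.
#' @return integer atom indices.
#' @export
select_atoms <- function(structure, spec, quiet = FALSE) {
  a <- structure$atoms
  in_range <- rep(FALSE, nrow(a))
  for (r in spec$ranges) {
    in_range <- in_range | (a$resnum >= r[1] & a$resnum <= r[2])
  }
  if (!is.na(spec$chain)) in_range <- in_range & a$chain == spec$chain
  if (spec$heavy_only) in_range <- in_range & is_heavy(structure)
  idx <- which(in_range)
  if (length(idx) == 0 && !quiet) {
    warning("region '", spec$name, "' selects no atoms")
  }
  idx
}

#' Annotate a glycan
#'
#' @param glycan_id label.
#' @param attachment `c(chain, resnum)` of the glycosylated residue.
#' @param linkage `"N"` or `"O"`.
#' @param atom_serials serial numbers of the glycan's pseudo-atoms.
#' @return a `glycan_annotation`.
#' @export
glycan_annotation <- function(glycan_id, attachment, linkage = c("N", "O"),
                              atom_serials) {
  linkage <- match.arg(linkage)
  atom_serials <- as.integer(atom_serials)
  if (length(atom_serials) == 0) stop("glycan must own at least one atom")
  structure(list(glycan_id = glycan_id,
                 attachment = list(chain = as.character(attachment[1]),
                                   resnum = as.integer(attachment[2])),
                 linkage = linkage,
                 atom_serials = atom_serials),
            class = "glycan_annotation")
}

.glycan_atom_indices <- function(structure, glycan) {
  match(glycan$atom_serials, structure$atoms$serial)
}

#' Assign glycans to a region by proximity
#'
#' A glycan belongs to a region when the minimum heavy-atom distance
#' between any of its atoms and any region atom is at or below `cutoff`
#' (inclusive; default 0.5 nm, i.e. the 5 Angstrom rule).
#'
#' @param structure topology.
#' @param glycans list of `glycan_annotation`.
#' @param region a `region_spec`.
#' @param coords frame coordinates (atoms x 3, nm); defaults to the
#'   structure's own coordinates.
#' @param cutoff nm, inclusive.
#' @return character vector of glycan ids.
#' @export
assign_glycans_to_region <- function(structure, glycans, region,
                                     coords = NULL, cutoff = 0.5) {
  if (is.null(coords)) coords <- structure$xyz
  ridx <- select_atoms(structure, region, quiet = TRUE)
  heavy <- is_heavy(structure)
  if (length(ridx) == 0 || length(glycans) == 0) return(character(0))
  rxyz <- coords[ridx, , drop = FALSE]
  hit <- vapply(glycans, function(g) {
    gidx <- .glycan_atom_indices(structure, g)
    gidx <- gidx[!is.na(gidx) & heavy[gidx]]
    if (length(gidx) == 0) return(FALSE)
    d2 <- crossdist2(coords[gidx, , drop = FALSE], rxyz)
    sqrt(min(d2)) <= cutoff
  }, logical(1))
  vapply(glycans[hit], `[[`, character(1), "glycan_id")
}

#' Read region and glycan definitions from a YAML config
#'
#' The config holds `regions:` (list with `name`, `chain`, `ranges`,
#' `heavy_only`) and optionally `glycans:` (list with `id`, `chain`,
#' `resnum`, `linkage`, `atom_serials`).
#'
#' @param path YAML file.
#' @return list with elements `regions` (named list of `region_spec`) and
#'   `glycans` (list of `glycan_annotation`).
#' @export
read_region_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  regions <- list()
  for (r in cfg$regions) {
    chain <- if (is.null(r$chain) || identical(r$chain, "*")) NA else r$chain
    heavy <- if (is.null(r$heavy_only)) TRUE else isTRUE(r$heavy_only)
    ranges <- lapply(r$ranges, function(p) c(p[[1]], p[[2]]))
    regions[[r$name]] <- region_spec(r$name, ranges, chain, heavy)
  }
  glycans <- lapply(cfg$glycans, function(g) {
    glycan_annotation(g$id, c(g$chain, g$resnum), g$linkage,
                      unlist(g$atom_serials))
  })
  list(regions = regions, glycans = glycans)
}

#' Write region and glycan definitions to a YAML config
#'
#' @param regions named list of `region_spec`.
#' @param glycans list of `glycan_annotation` (may be empty).
#' @param path output YAML path.
#' @export
write_region_config <- function(regions, glycans = list(), path) {
  cfg <- list(
    regions = unname(lapply(regions, function(r) {
      list(name = r$name,
           chain = if (is.na(r$chain)) "*" else r$chain,
           ranges = lapply(r$ranges, as.list),
           heavy_only = r$heavy_only)
    })),
    glycans = unname(lapply(glycans, function(g) {
      list(id = g$glycan_id, chain = g$attachment$chain,
           resnum = g$attachment$resnum, linkage = g$linkage,
           atom_serials = as.list(g$atom_serials))
    }))
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Default VWF mechanomodule region definitions
#'
#' The segment definitions used throughout: N- and C-terminal
#' autoinhibitory modules (1238-1271, 1459-1493), the A1 core and its
#' alignment anchor (1290-1430), the receptor span (GPIb-alpha 1-265), the
#' D'D3 region (764-1237), the N-terminal flanking peptide (1238-1267) and
#' the full mechanomodule span (764-1873).
#'
#' @return named list of `region_spec`.
#' @export
default_regions <- function() {
  path <- system.file("extdata", "vwf_regions.yaml", package = "vwfshield")
  read_region_config(path)$regions
}
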