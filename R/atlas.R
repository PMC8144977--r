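#' Seven-network parcel atlas utilities
#'
#' The package works on parcel-by-timepoint matrices labelled by a lookup
#' table in the style of the Schaefer 100-parcel parcellation grouped into
#' the seven Yeo networks. [synthetic_atlas()] builds the synthetic lookup
#' shipped with the package: 100 parcels, 50 per hemisphere, with
#' per-hemisphere network membership counts mimicking the real atlas, plus a
#' small temporoparietal-junction (TPJ) sub-ROI inside the ventral attention
#' network. Parcel geometry is not modelled; adjacency for cluster
#' correction comes from [parcel_lattice_adjacency()].
#'
#' @return A data.frame with columns `parcel_id` (1..100), `network` (one of
#'   the seven network labels), `hemisphere` (`"L"`/`"R"`) and `subroi`
#'   (`"TPJ"` for the TPJ parcels, `NA` otherwise).
#' @seealso [read_atlas()], [roi_definitions()]
#' @export
#' @examples
#' atlas <- synthetic_atlas()
#' table(atlas$network, atlas$hemisphere)
synthetic_atlas <- function() {
  counts <- c(
    Vis = 7L, SomMot = 8L, DorsAttn = 7L, SalVentAttn = 6L,
    Limbic = 5L, Cont = 6L, Default = 11L
  )
  stopifnot(sum(counts) == 50L)
  one_hemi <- rep(names(counts), counts)
  atlas <- data.frame(
    parcel_id = 1:100,
    network = c(one_hemi, one_hemi),
    hemisphere = rep(c("L", "R"), each = 50L),
    subroi = NA_character_,
    stringsAsFactors = FALSE
  )
  # First two ventral-attention parcels of each hemisphere form the TPJ sub-ROI.
  for (h in c("L", "R")) {
    van <- which(atlas$network == "SalVentAttn" & atlas$hemisphere == h)
    atlas$subroi[van[1:2]] <- "TPJ"
  }
  atlas
}

#' Canonical network vocabulary of the seven-network scheme
#' @return Character vector of the seven network labels.
#' @export
yeo7_networks <- function() {
  c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont", "Default")
}

.check_atlas <- function(atlas) {
  need <- c("parcel_id", "network", "hemisphere")
  miss <- setdiff(need, names(atlas))
  if (length(miss)) .stopf("atlas is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(atlas) == 0L) .stopf("atlas is empty")
  if (anyDuplicated(atlas$parcel_id)) {
    dup <- unique(atlas$parcel_id[duplicated(atlas$parcel_id)])
    .stopf("duplicate parcel id(s) in atlas: %s", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(atlas$network), yeo7_networks())
  if (length(bad)) .stopf("unknown network label(s): %s", paste(bad, collapse = ", "))
  if (!all(atlas$hemisphere %in% c("L", "R"))) {
    .stopf("atlas hemisphere must be 'L' or 'R'")
  }
  invisible(atlas)
}

#' ROI definitions used by the analyses
#'
#' Maps the field's ROI names onto atlas rows: DAN = dorsal attention
#' network, DMN = default mode network, VAN = ventral attention network and
#' TPJ = the ventral-attention sub-ROI.
#'
#' @param atlas An atlas lookup data.frame (see [synthetic_atlas()]).
#' @return Named list of integer parcel-id vectors.
#' @export
roi_definitions <- function(atlas = synthetic_atlas()) {
  .check_atlas(atlas)
  tpj <- if ("subroi" %in% names(atlas)) {
    atlas$parcel_id[!is.na(atlas$subroi) & atlas$subroi == "TPJ"]
  } else {
    integer(0)
  }
  list(
    DAN = atlas$parcel_id[atlas$network == "DorsAttn"],
    DMN = atlas$parcel_id[atlas$network == "Default"],
    VAN = atlas$parcel_id[atlas$network == "SalVentAttn"],
    TPJ = tpj
  )
}

#' Read / write an atlas lookup table
#'
#' Tab-delimited with header columns `parcel_id`, `network`, `hemisphere`
#' and optionally `subroi`. Every parcel must be mapped exactly once and the
#' network vocabulary is validated against the seven-network scheme.
#'
#' @param path File path.
#' @return `read_atlas` returns the validated atlas data.frame.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) .stopf("atlas file not found: %s", path)
  info <- file.info(path)
  if (isTRUE(info$size == 0)) .stopf("atlas file is empty: %s", path)
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_atlas(atlas)
  atlas
}

#' @rdname read_atlas
#' @param atlas Atlas data.frame.
#' @export
write_atlas <- function(atlas, path) {
  .check_atlas(atlas)
  utils::write.table(atlas, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Lattice adjacency over the synthetic parcellation
#'
#' Cluster-based correction needs a neighbourhood structure. Surface meshes
#' are out of scope here, so each hemisphere's 50 parcels are arranged on a
#' 10 x 5 grid (in parcel-id order) with 4-connectivity and no edges across
#' the midline. The family-wise-error behaviour of the permutation test, not
#' any particular geometry, is the contract.
#'
#' @param atlas Atlas lookup data.frame.
#' @param nrow_grid,ncol_grid Grid dimensions per hemisphere; their product
#'   must equal the number of parcels per hemisphere.
#' @return Adjacency list: for parcel `i`, `adj[[i]]` holds the integer ids
#'   of its neighbours. The relation is symmetric.
#' @export
parcel_lattice_adjacency <- function(atlas = synthetic_atlas(),
                                     nrow_grid = 10L, ncol_grid = 5L) {
  .check_atlas(atlas)
  adj <- vector("list", nrow(atlas))
  for (h in unique(atlas$hemisphere)) {
    ids <- atlas$parcel_id[atlas$hemisphere == h]
    if (length(ids) != nrow_grid * ncol_grid) {
      .stopf("hemisphere %s has %d parcels; grid is %d x %d",
             h, length(ids), nrow_grid, ncol_grid)
    }
    grid <- matrix(ids, nrow = nrow_grid, ncol = ncol_grid)
    for (i in seq_len(nrow_grid)) {
      for (j in seq_len(ncol_grid)) {
        nb <- c(
          if (i > 1L) grid[i - 1L, j],
          if (i < nrow_grid) grid[i + 1L, j],
          if (j > 1L) grid[i, j - 1L],
          if (j < ncol_grid) grid[i, j + 1L]
        )
        adj[[grid[i, j]]] <- as.integer(nb)
      }
    }
  }
  adj
}
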