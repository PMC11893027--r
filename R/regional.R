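#' Default 19-label to 7-category label mapping
#'
#' The fine parcellation produced by automated fetal-brain segmentation
#' (19 raw labels: left/right and substructure pairs) collapsed into the
#' seven analysis categories. Left/right pairs merge, the corpus callosum
#' joins white matter, the vermis joins the cerebellum category, and the
#' third/fourth ventricles join the lateral ventricles. The mapping ships
#' as an editable YAML file (`inst/extdata/label_mapping.yaml`); raw label
#' ids are a package convention.
#'
#' @param path Optional path to a YAML mapping file (`label id -> category`
#'   entries under a `mapping` key); default uses the packaged file.
#' @return Named integer vector: names are raw label ids, values merged
#'   category labels 1..7 (0 = discard).
#' @export
default_label_mapping <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "label_mapping.yaml",
                        package = "fetalt2star")
  }
  y <- yaml::read_yaml(path)
  cats <- c(discard = 0L, setNames(as.integer(names(region_names())),
                                   unname(region_names())))
  m <- vapply(y$mapping, function(cat) {
    if (!cat %in% names(cats)) stop("unknown category: ", cat)
    cats[[cat]]
  }, integer(1))
  setNames(m, names(y$mapping))
}

#' Merge raw parcellation labels into the seven analysis categories
#'
#' Relabels a fine-parcellation volume into the merged categories. Voxel
#' counts are conserved: each category's count is the sum of the counts of
#' its raw labels.
#'
#' @param raw A `label_volume` carrying raw label ids.
#' @param mapping Named integer vector as from [default_label_mapping()];
#'   must cover every nonzero label present.
#' @return A `label_volume` over labels `{0..7}`.
#' @export
merge_labels <- function(raw, mapping) {
  lab <- raw$labels
  present <- sort(unique(as.integer(lab[lab > 0])))
  unmapped <- setdiff(as.character(present), names(mapping))
  if (length(unmapped) > 0) {
    stop("unmapped label id(s) present: ", paste(unmapped, collapse = ", "))
  }
  lut <- integer(max(present) + 1)           # index = raw id + 1
  lut[as.integer(names(mapping)) + 1] <- as.integer(mapping)
  out <- array(0L, dim = dim(lab))
  nz <- lab > 0
  out[nz] <- lut[lab[nz] + 1L]
  structure(list(labels = out, affine = raw$affine,
                 voxel_size = raw$voxel_size, label_names = region_names()),
            class = "label_volume")
}

.voxel_volume_ml <- function(affine) {
  v <- abs(det(affine[1:3, 1:3]))
  if (v == 0) stop("singular affine: voxel volume is zero")
  v / 1000
}

#' Per-region mean T2* over valid voxels
#'
#' For each of the seven categories, the arithmetic mean of the T2* map
#' over voxels that belong to the category *and* carry a valid fit.
#' Categories without valid voxels are reported with an `NA` mean and
#' flagged.
#'
#' @param map A `t2star_map`.
#' @param labels A merged `label_volume` of matching shape.
#' @return Data frame with columns `region`, `mean_t2star_ms`,
#'   `voxel_count`, `n_valid_voxels`, `volume_ml`, `defined`.
#' @export
regional_mean_t2star <- function(map, labels) {
  if (!all(dim(map$t2star) == dim(labels$labels))) {
    stop("T2* map and label volume shapes differ")
  }
  vox_ml <- .voxel_volume_ml(labels$affine)
  nm <- region_names()
  out <- lapply(seq_along(nm), function(l) {
    in_reg <- labels$labels == l
    ok <- in_reg & map$validity
    n_ok <- sum(ok)
    data.frame(region = nm[[l]],
               mean_t2star_ms = if (n_ok > 0) mean(map$t2star[ok]) else NA_real_,
               voxel_count = sum(in_reg),
               n_valid_voxels = n_ok,
               volume_ml = sum(in_reg) * vox_ml,
               defined = n_ok > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-region volumes in millilitres
#'
#' Volume of each category from its voxel count times the voxel volume
#' (the absolute determinant of the affine's linear part, in mm^3).
#'
#' @param labels A merged `label_volume`.
#' @return Data frame with columns `region`, `voxel_count`, `volume_ml`.
#' @export
regional_volume <- function(labels) {
  vox_ml <- .voxel_volume_ml(labels$affine)
  nm <- region_names()
  counts <- vapply(seq_along(nm), function(l) sum(labels$labels == l),
                   numeric(1))
  data.frame(region = unname(nm), voxel_count = counts,
             volume_ml = counts * vox_ml, stringsAsFactors = FALSE)
}
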