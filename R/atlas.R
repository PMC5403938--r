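# Desikan-Killiany cortical atlas definition: 34 gyral regions per
# hemisphere, 68 network nodes in total.  The canonical node order is all
# left-hemisphere regions followed by all right-hemisphere regions, each
# hemisphere alphabetical by FreeSurfer StructName.  The order itself is a
# package convention (required for deterministic matrix layouts); any valid
# input file order is normalised to it at parse time.

.dk_struct_names <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
  "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
  "lateralorbitofrontal", "lingual", "medialorbitofrontal", "middletemporal",
  "paracentral", "parahippocampal", "parsopercularis", "parsorbitalis",
  "parstriangularis", "pericalcarine", "postcentral", "posteriorcingulate",
  "precentral", "precuneus", "rostralanteriorcingulate",
  "rostralmiddlefrontal", "superiorfrontal", "superiorparietal",
  "superiortemporal", "supramarginal", "temporalpole", "transversetemporal"
)

#' Desikan-Killiany atlas definition
#'
#' The 68 cortical regions used as network nodes: 34 gyrus-based parcels per
#' hemisphere.  Region labels are `lh_<StructName>` / `rh_<StructName>` and
#' the row order is the package's canonical node order (left hemisphere then
#' right, alphabetical within hemisphere).
#'
#' @return A data frame with columns `region` (unique label),
#'   `hemisphere` (`"lh"` or `"rh"`) and `struct_name` (FreeSurfer
#'   StructName), 68 rows.
#' @examples
#' atlas <- dk_atlas()
#' nrow(atlas)           # 68
#' table(atlas$hemisphere)
#' @export
dk_atlas <- function() {
  data.frame(
    region = dk_region_names(),
    hemisphere = rep(c("lh", "rh"), each = length(.dk_struct_names)),
    struct_name = rep(.dk_struct_names, 2L),
    stringsAsFactors = FALSE
  )
}

#' Canonical region labels
#'
#' @return Character vector of the 68 region labels in canonical order.
#' @export
dk_region_names <- function() {
  c(paste0("lh_", .dk_struct_names), paste0("rh_", .dk_struct_names))
}

#' FreeSurfer StructNames of the 34 per-hemisphere parcels
#'
#' @return Character vector of length 34, alphabetical.
#' @export
dk_struct_names <- function() {
  .dk_struct_names
}

#' Canonical morphometric feature names
#'
#' The nine regional morphometric features measured by surface
#' reconstruction, in the canonical column order used throughout the
#' package: vertex count (`NumVert`), surface area in mm^2 (`SurfArea`),
#' gray-matter volume in mm^3 (`GrayVol`), mean and standard deviation of
#' cortical thickness in mm (`ThickAvg`, `ThickStd`), mean curvature in
#' mm^-1 (`MeanCurv`), Gaussian curvature in mm^-2 (`GausCurv`), fold index
#' and curvature index (dimensionless).
#'
#' @return Character vector of length 9.
#' @export
morph_features <- function() {
  c("NumVert", "SurfArea", "GrayVol", "ThickAvg", "ThickStd",
    "MeanCurv", "GausCurv", "FoldInd", "CurvInd")
}

#' Approximate region centroid coordinates
#'
#' Per-region x/y/z coordinates used only for visualisation export
#' (`.node` files).  These are synthetic approximate MNI-space centroids
#' shipped with the package as a convenience; they are not derived from any
#' particular subject and should be replaced with study-specific centroids
#' for publication-quality figures.
#'
#' @return Data frame with columns `region`, `x`, `y`, `z` (68 rows,
#'   canonical order).
#' @export
dk_centroids <- function() {
  path <- system.file("extdata", "dk_centroids_synthetic.tsv",
                      package = "morphnet", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(identical(tab$region, dk_region_names()))
  tab
}
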