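# Canonical feature index: 148 Destrieux cortical thickness regions
# (74 labels x 2 hemispheres) + 21 FreeSurfer aseg subcortical volumes.

# aparc.a2009s label order as emitted by FreeSurfer's ?h.aparc.a2009s.stats
.destrieux_labels <- c(
  "G_and_S_frontomargin", "G_and_S_occipital_inf", "G_and_S_paracentral",
  "G_and_S_subcentral", "G_and_S_transv_frontopol", "G_and_S_cingul-Ant",
  "G_and_S_cingul-Mid-Ant", "G_and_S_cingul-Mid-Post",
  "G_cingul-Post-dorsal", "G_cingul-Post-ventral", "G_cuneus",
  "G_front_inf-Opercular", "G_front_inf-Orbital", "G_front_inf-Triangul",
  "G_front_middle", "G_front_sup", "G_Ins_lg_and_S_cent_ins",
  "G_insular_short", "G_occipital_middle", "G_occipital_sup",
  "G_oc-temp_lat-fusifor", "G_oc-temp_med-Lingual", "G_oc-temp_med-Parahip",
  "G_orbital", "G_pariet_inf-Angular", "G_pariet_inf-Supramar",
  "G_parietal_sup", "G_postcentral", "G_precentral", "G_precuneus",
  "G_rectus", "G_subcallosal", "G_temp_sup-G_T_transv", "G_temp_sup-Lateral",
  "G_temp_sup-Plan_polar", "G_temp_sup-Plan_tempo", "G_temporal_inf",
  "G_temporal_middle", "Lat_Fis-ant-Horizont", "Lat_Fis-ant-Vertical",
  "Lat_Fis-post", "Pole_occipital", "Pole_temporal", "S_calcarine",
  "S_central", "S_cingul-Marginalis", "S_circular_insula_ant",
  "S_circular_insula_inf", "S_circular_insula_sup", "S_collat_transv_ant",
  "S_collat_transv_post", "S_front_inf", "S_front_middle", "S_front_sup",
  "S_interm_prim-Jensen", "S_intrapariet_and_P_trans",
  "S_oc_middle_and_Lunatus", "S_oc_sup_and_transversal", "S_occipital_ant",
  "S_oc-temp_lat", "S_oc-temp_med_and_Lingual", "S_orbital_lateral",
  "S_orbital_med-olfact", "S_orbital-H_Shaped", "S_parieto_occipital",
  "S_pericallosal", "S_postcentral", "S_precentral-inf-part",
  "S_precentral-sup-part", "S_suborbital", "S_subparietal",
  "S_temporal_inf", "S_temporal_sup", "S_temporal_transverse"
)

# 21 aseg structures: 10 bilateral pairs + brain stem. The exact subcortical
# label set is a package convention (aseg offers more structures than the 21
# used here); it is fixed so that column order is stable across runs.
.aseg_bilateral <- c(
  "Lateral-Ventricle", "Thalamus-Proper", "Caudate", "Putamen", "Pallidum",
  "Hippocampus", "Amygdala", "Accumbens-area", "VentralDC",
  "Cerebellum-Cortex"
)

#' Canonical region index
#'
#' Returns the ordered list of the 169 features the pipeline operates on:
#' 148 cortical-thickness regions (74 Destrieux labels per hemisphere, left
#' hemisphere first) followed by 21 subcortical volumes (10 bilateral aseg
#' structures plus the brain stem). All deviation, outlier and Hamming
#' computations use this column order.
#'
#' @return A data frame with columns `name` (unique column label), `label`
#'   (atlas label without hemisphere prefix), `hemisphere`
#'   (`"left"`, `"right"` or `"midline"`) and `kind`
#'   (`"cortical_thickness"`, in mm, or `"subcortical_volume"`, in mm^3).
#' @examples
#' idx <- region_index()
#' nrow(idx)            # 169
#' table(idx$kind)
#' @export
region_index <- function() {
  cortical <- data.frame(
    name = c(paste0("lh_", .destrieux_labels), paste0("rh_", .destrieux_labels)),
    label = rep(.destrieux_labels, 2L),
    hemisphere = rep(c("left", "right"), each = length(.destrieux_labels)),
    kind = "cortical_thickness",
    stringsAsFactors = FALSE
  )
  subcortical <- data.frame(
    name = c(paste0("Left-", .aseg_bilateral), paste0("Right-", .aseg_bilateral),
             "Brain-Stem"),
    label = c(.aseg_bilateral, .aseg_bilateral, "Brain-Stem"),
    hemisphere = c(rep(c("left", "right"), each = length(.aseg_bilateral)),
                   "midline"),
    kind = "subcortical_volume",
    stringsAsFactors = FALSE
  )
  out <- rbind(cortical, subcortical)
  rownames(out) <- NULL
  out
}

#' Region names in canonical order
#'
#' @param index A region index data frame, by default [region_index()].
#' @return Character vector of region column names.
#' @export
region_names <- function(index = region_index()) {
  index$name
}

# Internal: check that a region index is well formed.
validate_region_index <- function(index) {
  stopifnot(is.data.frame(index),
            all(c("name", "hemisphere", "kind") %in% names(index)))
  if (anyDuplicated(index$name))
    stop("region index contains duplicated names", call. = FALSE)
  if (!all(index$kind %in% c("cortical_thickness", "subcortical_volume")))
    stop("region kind must be cortical_thickness or subcortical_volume",
         call. = FALSE)
  invisible(index)
}
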