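#' Built-in AAL-90 region lookup
#'
#' The standard 90-region automated anatomical labeling parcellation
#' (cortical and subcortical regions; cerebellum excluded), labels 1-90 in
#' the conventional left/right-interleaved order. MNI centroids are provided
#' for the five regions most often reported as conversion-related hubs
#' (precentral L, inferior frontal operculum L, lingual R, precuneus L,
#' inferior temporal L); the remaining centroids are NA — hub reporting only
#' needs names, and atlas images carry their own geometry.
#'
#' @return data.frame with columns `label`, `name`, `x_mni`, `y_mni`,
#'   `z_mni`, `lobe`.
#' @export
#' @examples
#' head(aal90Lookup())
aal90Lookup <- function() {
  base <- c(
    "Precentral", "Frontal_Sup", "Frontal_Sup_Orb", "Frontal_Mid",
    "Frontal_Mid_Orb", "Frontal_Inf_Oper", "Frontal_Inf_Tri",
    "Frontal_Inf_Orb", "Rolandic_Oper", "Supp_Motor_Area", "Olfactory",
    "Frontal_Sup_Medial", "Frontal_Med_Orb", "Rectus", "Insula",
    "Cingulum_Ant", "Cingulum_Mid", "Cingulum_Post", "Hippocampus",
    "ParaHippocampal", "Amygdala", "Calcarine", "Cuneus", "Lingual",
    "Occipital_Sup", "Occipital_Mid", "Occipital_Inf", "Fusiform",
    "Postcentral", "Parietal_Sup", "Parietal_Inf", "SupraMarginal",
    "Angular", "Precuneus", "Paracentral_Lobule", "Caudate", "Putamen",
    "Pallidum", "Thalamus", "Heschl", "Temporal_Sup", "Temporal_Pole_Sup",
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf")
  lobe45 <- c(rep("frontal", 14), "insula", rep("limbic", 3),
              rep("limbic", 3), rep("occipital", 7),
              rep("parietal", 7), rep("subcortical", 4), "temporal",
              rep("temporal", 5))
  name <- as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
  lobe <- rep(lobe45, each = 2L)
  lk <- data.frame(label = 1:90, name = name,
                   x_mni = NA_real_, y_mni = NA_real_, z_mni = NA_real_,
                   lobe = lobe, stringsAsFactors = FALSE)
  known <- data.frame(
    label = c(1L, 11L, 48L, 67L, 89L),
    x = c(-38.65, -48.43, 16.29, 9.98, -49.77),
    y = c(-5.68, 12.73, -66.93, -56.05, 28.05),
    z = c(50.94, 19.02, -3.87, 43.77, -23.17))
  m <- match(known$label, lk$label)
  lk$x_mni[m] <- known$x
  lk$y_mni[m] <- known$y
  lk$z_mni[m] <- known$z
  lk
}
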