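#' AAL-116 parcellation labels
#'
#' Region names of the 116-region Automated Anatomical Labeling scheme used
#' as the default labeling convention for whole-brain connectomes: 90
#' cerebral regions (45 left/right pairs) followed by 26 cerebellar regions.
#' The `category` attribute classifies each region as cortical (78),
#' subcortical (12) or cerebellar (26).
#'
#' @return character vector of 116 labels with a `category` attribute
#'   (factor with levels cortical, subcortical, cerebellar).
#' @examples
#' table(attr(aalRegionLabels(), "category"))
#' @export
aalRegionLabels <- function() {
  cerebral <- c(
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
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  subcorticalStems <- c("Hippocampus", "Amygdala", "Caudate", "Putamen",
                        "Pallidum", "Thalamus")
  cerebellar <- c(
    paste0("Cerebelum_", rep(c("Crus1", "Crus2", "3", "4_5", "6", "7b",
                               "8", "9", "10"), each = 2), c("_L", "_R")),
    paste0("Vermis_", c("1_2", "3", "4_5", "6", "7", "8", "9", "10"))
  )
  labels <- c(paste0(rep(cerebral, each = 2), c("_L", "_R")), cerebellar)
  stopifnot(length(labels) == 116L)
  category <- factor(
    c(ifelse(rep(cerebral, each = 2) %in% subcorticalStems,
             "subcortical", "cortical"),
      rep("cerebellar", length(cerebellar))),
    levels = c("cortical", "subcortical", "cerebellar")
  )
  attr(labels, "category") <- category
  labels
}
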