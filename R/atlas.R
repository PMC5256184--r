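#' AAL-derived 92-region node labels
#'
#' Returns the default node labelling used throughout the package: the 90
#' cerebral regions of the Automated Anatomical Labeling (AAL) atlas in their
#' conventional left/right interleaved order, followed by one composite
#' cerebellar region per hemisphere, giving 92 graph nodes in total.
#'
#' @return Character vector of length 92.
#' @examples
#' labels <- aal92_labels()
#' length(labels)
#' grep("Thalamus", labels, value = TRUE)
#' @export
aal92_labels <- function() {
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
  c(paste0(rep(cerebral, each = 2L), c("_L", "_R")),
    "Cerebelum_L", "Cerebelum_R")
}

# Internal: default labels for an arbitrary node count.
default_node_labels <- function(n_nodes) {
  if (n_nodes == 92L) aal92_labels() else sprintf("roi_%03d", seq_len(n_nodes))
}
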