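#' AAL-90 region labels
#'
#' Ordered labels of the first 90 regions of the Automated Anatomical
#' Labelling atlas (cortical and subcortical parcels, alternating
#' left/right hemisphere), the parcellation used for source-level
#' connectivity throughout the package. The right posterior cingulate
#' gyrus carries the label \code{"Cingulum_Post_R"} (index 36).
#'
#' @return Character vector of length 90.
#' @export
#' @examples
#' aal90_labels()[36]
aal90_labels <- function() {
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
    "Temporal_Mid", "Temporal_Pole_Mid", "Temporal_Inf"
  )
  as.vector(rbind(paste0(base, "_L"), paste0(base, "_R")))
}

#' Canonical hub label: right posterior cingulate gyrus
#' @keywords internal
.hub_label_default <- "Cingulum_Post_R"

# Labels for a reduced network: the first n AAL labels, with the designated
# hub label substituted in (last position) when the truncation would drop it.
roi_labels_for <- function(n_nodes, hub_label = .hub_label_default) {
  all_labels <- aal90_labels()
  if (n_nodes > length(all_labels)) {
    stop("n_nodes must be <= ", length(all_labels))
  }
  labels <- all_labels[seq_len(n_nodes)]
  if (!hub_label %in% labels) {
    labels[n_nodes] <- hub_label
  }
  labels
}
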