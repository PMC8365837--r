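# Region naming for the 102-region parcellation: the 90 cerebral AAL regions
# with the two thalami replaced, in place, by seven paired thalamic
# subregions (anterior, medial dorsal, lateral dorsal, lateral posterior,
# ventral lateral posterior, medial pulvinar, lateral pulvinar).

.aalPairNames <- c(
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

.thalamicPairNames <- c(
  "Thalamus_Ant", "Thalamus_MedDorsal", "Thalamus_LatDorsal",
  "Thalamus_LatPosterior", "Thalamus_VentLatPosterior",
  "Thalamus_MedPulvinar", "Thalamus_LatPulvinar")

.pairToLR <- function(pairs) {
  out <- character(2L * length(pairs))
  out[seq_along(pairs) * 2L - 1L] <- paste0(pairs, "_L")
  out[seq_along(pairs) * 2L] <- paste0(pairs, "_R")
  out
}

#' Cerebral AAL region labels
#'
#' The 90 cerebral regions of the Automated Anatomical Labeling atlas
#' (cerebellum excluded), as left/right pairs in atlas order.
#'
#' @return character vector of 90 region labels.
#' @export
#' @examples
#' length(aalCerebralLabels())  # 90
aalCerebralLabels <- function() .pairToLR(.aalPairNames)

#' Paired thalamic subregion labels
#'
#' The seven thalamic subregions (anterior, medial dorsal, lateral dorsal,
#' lateral posterior, ventral lateral posterior, medial pulvinar, lateral
#' pulvinar) as left/right pairs.
#'
#' @return character vector of 14 labels.
#' @export
thalamicSubregionLabels <- function() .pairToLR(.thalamicPairNames)

#' The modified 102-region parcellation
#'
#' The cerebral AAL parcellation with the left and right thalamus labels
#' replaced, in place, by the seven paired thalamic subregions, giving 102
#' regions.
#'
#' @return character vector of 102 region labels.
#' @export
#' @examples
#' length(modifiedParcellation())  # 102
modifiedParcellation <- function() {
  base <- aalCerebralLabels()
  i <- match(c("Thalamus_L", "Thalamus_R"), base)
  c(base[seq_len(i[1] - 1L)], thalamicSubregionLabels(),
    base[seq(i[2] + 1L, length(base))])
}

#' Left/right label pairs of the thalamic subregions
#'
#' Convenience table of the seven thalamic subregion pairs (optionally plus
#' the composite whole-thalamus pair) used for lateralized group comparisons.
#' The anterior nucleus carries the a-priori hypothesis; all other rows are
#' exploratory.
#'
#' @param includeWhole also list the composite whole-thalamus pair
#'   (labels `Thalamus_L` / `Thalamus_R`), computed by the pipeline as the
#'   per-side mean of the seven subregion series.
#' @return data.frame with columns `name`, `left`, `right`, `aPriori`.
#' @export
thalamicRegionPairs <- function(includeWhole = TRUE) {
  nm <- .thalamicPairNames
  out <- data.frame(name = nm, left = paste0(nm, "_L"),
                    right = paste0(nm, "_R"),
                    aPriori = nm == "Thalamus_Ant",
                    stringsAsFactors = FALSE)
  if (includeWhole)
    out <- rbind(out, data.frame(name = "Thalamus", left = "Thalamus_L",
                                 right = "Thalamus_R", aPriori = FALSE))
  out
}
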