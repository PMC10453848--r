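## Published benchmark tallies used as fixed numeric inputs for metric
## replication checks.

#' Reference confusion counts for OCT pathology classifiers
#'
#' Published confusion-matrix tallies (TP/FP/TN/FN) and the metric values
#' printed alongside them, for binary IRF/SRF/PED classifiers evaluated on a
#' 52,650-image OCT B-scan test set under three model variants: a classifier
#' trained on raw speckled images ("noisy"), the full-size
#' Inception-ResNet-v2 trained on despeckled images ("gcds"), and its
#' reduced small variant ("small_gcds"). These tallies are fixed inputs for
#' verifying that [classification_metrics()] reproduces the printed
#' accuracy/precision/sensitivity/specificity/F1 values at their printed
#' 4-decimal precision.
#'
#' One printed cell (IRF, small_gcds, accuracy = 0.9284) is inconsistent
#' with its own tallies, which imply (8556 + 40340) / 52650 = 0.9287 under
#' the accuracy definition; the tallies are authoritative for that cell.
#'
#' @return Data frame with columns `pathology`, `model`, `tp`, `fp`, `tn`,
#'   `fn`, `accuracy`, `precision`, `sensitivity`, `specificity`, `f1`.
#' @export
reference_confusion_counts <- function() {
  df <- read.csv(text = "
pathology,model,tp,fp,tn,fn,accuracy,precision,sensitivity,specificity,f1
IRF,noisy,8797,2919,40224,710,0.9310,0.7508,0.9253,0.9323,0.8290
IRF,gcds,8407,2213,40930,1100,0.9370,0.7916,0.8842,0.9487,0.8353
IRF,small_gcds,8556,2803,40340,951,0.9284,0.7532,0.9000,0.9350,0.8201
SRF,noisy,2182,613,49641,214,0.9842,0.7806,0.9106,0.9878,0.8406
SRF,gcds,2291,1161,49093,105,0.9759,0.6636,0.9561,0.9768,0.7835
SRF,small_gcds,2017,365,49889,379,0.9859,0.8468,0.8418,0.9927,0.8443
PED,noisy,2714,2511,46434,991,0.9334,0.5194,0.7325,0.9486,0.6078
PED,gcds,2699,2795,46150,1006,0.9278,0.4913,0.7285,0.9429,0.5868
PED,small_gcds,2531,1464,47481,1174,0.9499,0.6335,0.6831,0.9701,0.6574
", stringsAsFactors = FALSE)
  df
}
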