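# Printed reference tables from a published large-scale off-target
# profiling campaign of 2766 FDA-approved drugs. They serve as worked-
# example inputs: class-level interaction counts, headline ratio counts, and
# the 14-drug clinical-exposure panel. Values are transcribed as printed;
# arithmetic (floor percents, pCmax) is recomputed by this package.

#' Class-level interaction counts from the published profiling campaign
#'
#' Total predicted, unconfirmed and in-vitro-confirmed interaction counts
#' per therapeutic target class for 2766 FDA-approved drugs, as printed.
#' The percent-confirmed column is deliberately omitted: it is recomputed
#' with [floor_percent()].
#'
#' @return Tibble `target_class`, `total_predicted`, `predicted_unconfirmed`,
#'   `confirmed`, `printed_pct`.
#' @export
reference_class_counts <- function() {
  tibble::tribble(
    ~target_class,     ~total_predicted, ~predicted_unconfirmed, ~confirmed, ~printed_pct,
    "GPCR",            10650L,           5708L,                  4942L,      46L,
    "Enzyme",          4081L,            1374L,                  2707L,      66L,
    "Kinase",          3768L,            688L,                   3080L,      81L,
    "NuclearReceptor", 1293L,            684L,                   609L,       47L,
    "OtherFamilies",   605L,             197L,                   408L,       67L,
    "Transporter",     1788L,            651L,                   1137L,      63L,
    "Unclassified",    1057L,            429L,                   628L,       59L,
    "Cytochrome",      2827L,            36L,                    2791L,      98L,
    "IonChannel",      1303L,            322L,                   981L,       75L
  )
}

#' Headline counts from the published profiling campaign
#'
#' The counts behind the published ratio statistics: total predictions and
#' confirmations, dataset size, the GPCR and kinase subsets, and the
#' 14-drug exposure panel.
#'
#' @return Named list of integer counts.
#' @export
reference_headline_counts <- function() {
  list(
    n_drugs = 2766L,
    n_predicted = 27371L,
    n_confirmed = 17283L,
    gpcr_interactions = 10648L,
    gpcr_drugs = 1471L,
    kinase_interactions = 3768L,
    kinase_drugs = 283L,
    panel_drugs = 14L,
    panel_predicted = 899L,
    panel_confirmed = 859L
  )
}

#' The 14-drug clinical-exposure panel
#'
#' Approved drugs with printed free-plasma Cmax (uM), the printed pCmax, the
#' printed count of off-targets with measured pIC50 > 6.0, and the intended
#' targets. One row (Sirolimus) has a printed pCmax that is not reproducible
#' from its printed Cmax by rounding (0.0160 uM gives 7.80, printed 7.78);
#' `pcmax_reconcilable` records this.
#'
#' @return Tibble `drug_id`, `intended_targets`, `cmax_um`, `printed_pcmax`,
#'   `n_sub_um_printed`, `pcmax_reconcilable`.
#' @export
reference_drug_exposures <- function() {
  tibble::tribble(
    ~drug_id,             ~intended_targets,         ~cmax_um, ~printed_pcmax, ~n_sub_um_printed, ~pcmax_reconcilable,
    "Afatinib",           "EGFR, HER2, HER4",        0.0520,   7.28,           11L,               TRUE,
    "Bosutinib",          "BCR-Abl, Src",            0.3770,   6.42,           50L,               TRUE,
    "Celecoxib",          "COX-2",                   4.6000,   5.34,           19L,               TRUE,
    "Ceritinib",          "ALK",                     1.2100,   5.92,           17L,               TRUE,
    "Erlotinib",          "EGFR",                    3.1500,   5.50,           25L,               TRUE,
    "Finasteride",        "5-Alpha Reductase",       0.1240,   6.91,           4L,                TRUE,
    "Gefitinib",          "EGFR",                    0.3560,   6.45,           21L,               TRUE,
    "Hydroxychloroquine", "Cathepsin L",             0.3500,   6.46,           8L,                TRUE,
    "Imiquimod",          "TLR7R",                   0.0056,   8.25,           5L,                TRUE,
    "Lapatinib",          "ERBB2, EGFR",             4.1800,   5.38,           11L,               TRUE,
    "Olaparib",           "PARP",                    13.1000,  4.88,           9L,                TRUE,
    "Sirolimus",          "mTOR",                    0.0160,   7.78,           12L,               FALSE,
    "Tamoxifen Citrate",  "Estrogen Receptor",       0.1080,   6.97,           21L,               TRUE,
    "Teniposide",         "Topoisomerase II",        23.1000,  4.64,           9L,                TRUE
  )
}
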