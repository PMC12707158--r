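#' Genes with established tetralogy of Fallot associations
#'
#' `tof_training_genes` is the 53-gene training set used to learn the
#' TOF-specific annotation pattern: genes whose causal role in human
#' tetralogy of Fallot is supported by reviews, OMIM/StatPearls entries
#' and/or multiple case reports. It is a curated high-confidence set, not a
#' comprehensive list of every reported TOF association.
#'
#' `tof_established_genes` lists additional genes in which cohort
#' individuals carried pathogenic or likely pathogenic variants and whose
#' TOF association was already clearly established; together with the
#' training set they form the default "known gene" registry against which
#' phenotypic-expansion candidates are screened (see
#' [known_gene_registry()]).
#'
#' @format Character vectors of HGNC gene symbols.
#' @seealso [known_gene_registry()], [tof_candidate_evidence()]
#' @export
tof_training_genes <- c(
  "ALDH1A2", "CACNA1C", "CFC1", "CHD4", "CHD7", "CITED2", "CXCR4",
  "DOCK6", "EP300", "FGF8", "FLNA", "FLT4", "FOXC1", "FOXC2", "FOXH1",
  "GATA4", "GATA5", "GATA6", "GDF1", "HAND1", "HAND2", "ISL1", "JAG1",
  "KDM6A", "KDR", "KMT2C", "KMT2D", "KRAS", "MESP1", "MKKS", "NAA15",
  "NFATC1", "NKX2-5", "NKX2-6", "NODAL", "NOTCH1", "NOTCH2", "PITX2",
  "PTPN11", "RAF1", "RBM10", "ROBO1", "SALL1", "SMAD4", "SMARCC2",
  "SOS1", "TBX1", "TBX2", "TBX5", "TBX20", "TDGF1", "WASHC5", "ZFPM2"
)

#' @rdname tof_training_genes
#' @export
tof_established_genes <- c(
  "BRAF", "CDK13", "CHD4", "CHD7", "DOCK6", "EP300", "FLT4", "FOXC2",
  "JAG1", "KMT2D", "NAA15", "NOTCH1", "RBM10", "SMAD4", "SMARCA4", "WASHC5"
)

#' Evidence table for the four supported TOF expansion candidate genes
#'
#' Returns the published evidence rows for the four candidate genes that
#' met the phenotypic-expansion decision rule: the TOF-specific rank
#' annotation score, whether TOF cases involving the gene or its syndrome
#' have been reported in the literature, whether CHD has been observed in
#' mouse models of the gene's homolog, and the highest diagnostic certainty
#' the gene reached in the cohort.
#'
#' @return A data.frame with columns `gene`, `rank_score` (percent),
#'   `literature_cases`, `mouse_chd`, `diagnosis_certainty`.
#' @examples
#' ev <- tof_candidate_evidence()
#' evaluate_expansion(ev$gene, ev$rank_score, ev$literature_cases, ev$mouse_chd)
#' @export
tof_candidate_evidence <- function() {
  data.frame(
    gene = c("DVL3", "MED13L", "PUF60", "MEIS2"),
    rank_score = c(96.8, 85.1, 79.9, 61.9),
    literature_cases = c(TRUE, TRUE, TRUE, TRUE),
    mouse_chd = c(TRUE, FALSE, FALSE, TRUE),
    diagnosis_certainty = c("probable", "definitive", "definitive", "probable"),
    stringsAsFactors = FALSE
  )
}
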