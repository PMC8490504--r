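#' Tryptophan-pathway analyte panel
#'
#' The seven serum analytes measured by the multiplexed assay, ordered along
#' the kynurenine pathway. `pathway_distance` counts enzymatic steps away from
#' tryptophan (Trp) in the pathway schematic: Trp (0); 5-hydroxy-tryptophan
#' and N-formylkynurenine (1, the serotonin-branch and kynurenine-branch first
#' steps); kynurenine (2); 3-hydroxy-kynurenine and anthranilic acid (3);
#' 3-hydroxy-anthranilic acid (4). `technical_cv` is the default per-analyte
#' multiplicative measurement coefficient of variation used by the simulator.
#'
#' @return A tibble with columns `analyte`, `pathway_distance`,
#'   `producing_enzymes` (list column) and `technical_cv`.
#' @examples
#' kp_analytes()
#' @export
kp_analytes <- function() {
  tibble::tibble(
    analyte = c("Trp", "OH-Trp", "FK", "Kyn", "OH-Kyn", "AA", "OH-AA"),
    pathway_distance = c(0L, 1L, 1L, 2L, 3L, 3L, 4L),
    producing_enzymes = list(
      character(0),
      c("TPH1", "TPH2"),
      c("IDO1", "TDO2"),
      "AFMID",
      "KMO",
      "KYNU",
      "KYNU"
    ),
    technical_cv = c(0.05, 0.10, 0.12, 0.06, 0.12, 0.10, 0.15)
  )
}

#' @rdname kp_analytes
#' @export
kp_analyte_names <- function() kp_analytes()$analyte

#' Genes of the kynurenine-pathway kinetic model
#'
#' Enzyme genes (plus the amino-acid transporter SLC7A5 mediating Trp uptake)
#' that the expression-scaled kinetic model requires.
#'
#' @return Character vector of gene symbols.
#' @export
kp_genes <- function() {
  c("TPH1", "TPH2", "IDO1", "TDO2", "AFMID", "KMO", "KYNU", "HAAO", "SLC7A5")
}
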