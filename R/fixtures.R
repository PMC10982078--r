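# Accessors for the published reference tables shipped with the package.

#' Published tenuivirus RdRp p-distance matrix and clade groups
#'
#' The pairwise p-distance matrix (percent, as printed, one decimal) of
#' *Cimex* tenui-like virus 1 RdRp coding sequences from a worldwide bed
#' bug virome survey, with three rice/maize tenuivirus outgroup sequences
#' (RHBTV, RSV, MSTV), and the clade assignment used for the
#' phylogeographic summary: the Italian samples, the rest-of-the-world
#' samples, and the outgroup. Distances are returned as fractions
#' (divide-by-100) so they plug straight into [group_mean_distances()].
#'
#' @return list with `d` (11 x 11 symmetric fractional matrix) and
#'   `groups` (data.frame `seq_id`, `group`).
#' @examples
#' ref <- tenuivirus_reference_distances()
#' group_mean_distances(ref$d, ref$groups)
#' @export
tenuivirus_reference_distances <- function() {
  d <- read_distance_tsv(system.file("extdata",
                                     "tenuivirus_rdrp_pdistance.tsv",
                                     package = "cimexvir",
                                     mustWork = TRUE)) / 100
  groups <- read_groups_tsv(system.file("extdata",
                                        "tenuivirus_clade_groups.tsv",
                                        package = "cimexvir",
                                        mustWork = TRUE))
  list(d = d, groups = groups)
}

#' Published per-sample virus and Wolbachia read percentages
#'
#' The 22-sample table of read percentages mapped to the viruses detected
#' in a worldwide bed bug virome survey and to the *Wolbachia*
#' endosymbiont of *Cimex lectularius*, used for the abundance
#' regression. One sample (Ohio-USA 1, *Wolbachia* 14.90%) is a potential
#' outlier; [correlate_abundance()]'s `drop_samples` can exclude it, the
#' published fit keeps it.
#'
#' @return data.frame with `sample`, `pct_virus`, `pct_wolbachia`
#'   (22 rows).
#' @examples
#' correlate_abundance(wolbachia_virus_read_pct())
#' @export
wolbachia_virus_read_pct <- function() {
  read_abundance_tsv(system.file("extdata", "virus_wolbachia_read_pct.tsv",
                                 package = "cimexvir", mustWork = TRUE))
}
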