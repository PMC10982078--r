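#' Parse a BLAST/DIAMOND tabular hit file and filter by e-value
#'
#' Reads the 12-column tabular format (`outfmt 6`: `qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`;
#' extra trailing columns are tolerated and ignored) and drops hits with
#' e-value above the cutoff. The number of dropped rows is reported with
#' a message — the filter must never lose rows silently.
#'
#' @param path path to the tabular file (no header line).
#' @param evalue_cutoff maximum e-value retained (default `1e-5`).
#' @return data.frame with the 12 standard columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `evalue`, `bitscore`).
#' @export
parse_blast_tab <- function(path, evalue_cutoff = 1e-5) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    message("0 hit(s) dropped at e-value cutoff ", format(evalue_cutoff))
    out <- as.data.frame(setNames(
      c(rep(list(character()), 2L), rep(list(numeric()), 10L)), cols),
      stringsAsFactors = FALSE)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  short <- which(nf < 12L)
  if (length(short)) {
    stop(sprintf("line %d has %d columns; expected at least 12",
                 short[1L], nf[short[1L]]))
  }
  df <- as.data.frame(do.call(rbind, lapply(parts, `[`, 1:12)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  for (nm in cols[3:12]) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf("line %d: cannot parse %s value '%s'",
                   bad, nm, df[[nm]][bad]))
    }
    df[[nm]] <- v
  }
  if (any(df$evalue < 0)) stop("negative e-value")
  keep <- df$evalue <= evalue_cutoff
  message(sum(!keep), " hit(s) dropped at e-value cutoff ",
          format(evalue_cutoff))
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a presence matrix from per-sample transcript catalogs
#'
#' Turns per-sample sets of observed transcript-cluster IDs into the 0/1
#' presence matrix the co-occurrence screen consumes, and groups the
#' RdRp-confirmed clusters into one [anchor_set()] per virus. Transcript
#' IDs must be cluster IDs shared across samples (clustering, e.g. at 90%
#' identity, happens upstream).
#'
#' @param catalogs named list: sample ID -> character vector of observed
#'   cluster IDs.
#' @param anchor_annotation data.frame with columns `transcript_id`,
#'   `virus_id`, `complete_rdrp` (logical); rows with
#'   `complete_rdrp = TRUE` define the anchors.
#' @return list with `matrix` (0/1 integer matrix) and `anchors` (named
#'   list of `anchor_set`, one per virus; empty if no annotation rows are
#'   flagged).
#' @examples
#' cats <- list(s1 = c("c1", "c2"), s2 = "c1")
#' ann <- data.frame(transcript_id = "c1", virus_id = "v1",
#'                   complete_rdrp = TRUE)
#' build_presence_matrix(cats, ann)
#' @export
build_presence_matrix <- function(catalogs, anchor_annotation = NULL) {
  if (!is.list(catalogs) || length(catalogs) == 0L ||
      is.null(names(catalogs)) || !all(nzchar(names(catalogs)))) {
    stop("catalogs must be a nonempty named list of transcript ID vectors")
  }
  transcripts <- sort(unique(unlist(catalogs, use.names = FALSE)))
  if (length(transcripts) == 0L) stop("empty catalogs: no transcripts observed")
  m <- vapply(transcripts, function(tr) {
    vapply(catalogs, function(cat) as.integer(tr %in% cat), integer(1))
  }, integer(length(catalogs)))
  m <- matrix(m, nrow = length(catalogs),
              dimnames = list(names(catalogs), transcripts))
  check_presence_matrix(m)

  anchors <- list()
  if (!is.null(anchor_annotation)) {
    stopifnot(all(c("transcript_id", "virus_id", "complete_rdrp") %in%
                    names(anchor_annotation)))
    flagged <- anchor_annotation[as.logical(anchor_annotation$complete_rdrp), ,
                                 drop = FALSE]
    absent <- setdiff(flagged$transcript_id, transcripts)
    if (length(absent)) {
      stop("anchor cluster(s) absent from all samples: ",
           paste(absent, collapse = ", "))
    }
    sp <- split(flagged$transcript_id, flagged$virus_id)
    anchors <- mapply(anchor_set, names(sp), sp, SIMPLIFY = FALSE)
  }
  list(matrix = m, anchors = anchors)
}

#' Configure an end-to-end analysis run
#'
#' Bundles input paths and analysis parameters for [run_report()]. The
#' presence matrix and anchors are required; the transcript FASTA (for
#' ORF lengths), alignment + groups (for distance summaries) and the
#' abundance table (for the regression) are each optional — missing
#' stages are skipped and noted in the run log.
#'
#' @param matrix_path presence TSV (see [write_presence_tsv()]).
#' @param anchors_path anchors TSV (`virus_id`, `transcript_id`).
#' @param fasta_path optional transcript FASTA for ORF screening.
#' @param alignment_path,groups_path optional aligned FASTA + group TSV.
#' @param abundance_path optional abundance TSV.
#' @param out_dir output directory (created if absent).
#' @param v_threshold,t_threshold,min_orf_len screen thresholds
#'   (see [screen_config()]).
#' @param orf_mode ORF semantics (see [find_orfs()]).
#' @param distance_policy deletion policy (see [distance_matrix()]).
#' @return an object of class `run_config`.
#' @export
run_config <- function(matrix_path, anchors_path, fasta_path = NULL,
                       alignment_path = NULL, groups_path = NULL,
                       abundance_path = NULL, out_dir,
                       v_threshold = 0.75, t_threshold = 0.5,
                       min_orf_len = 500L, orf_mode = "stop_to_stop_nt",
                       distance_policy = "pairwise_deletion") {
  for (p in c(matrix_path, anchors_path, fasta_path, alignment_path,
              groups_path, abundance_path)) {
    if (!is.null(p) && !file.exists(p)) stop("input path does not exist: ", p)
  }
  structure(list(matrix_path = matrix_path, anchors_path = anchors_path,
                 fasta_path = fasta_path, alignment_path = alignment_path,
                 groups_path = groups_path, abundance_path = abundance_path,
                 out_dir = out_dir,
                 screen = screen_config(v_threshold, t_threshold, min_orf_len),
                 orf_mode = orf_mode, distance_policy = distance_policy),
            class = "run_config")
}

#' Run the full post-assembly analysis and write a report bundle
#'
#' Orchestrates the pipeline: candidate-segment screen (per virus in the
#' anchors file), optional distance-matrix and group-mean summaries,
#' optional abundance regression. Writes, under `out_dir`:
#' `candidates_<virus>.tsv`, `distance_matrix.tsv`, `group_means.tsv`,
#' `regression.json`, and `report.json` (thresholds, package version,
#' per-stage status and record counts). Outputs are deterministic —
#' rerunning the same config yields byte-identical files.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory stage results and the
#'   report structure.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(package = "cimexvir",
              version = as.character(packageVersion("cimexvir")),
              thresholds = unclass(config$screen),
              orf_mode = config$orf_mode,
              distance_policy = config$distance_policy,
              stages = list())
  results <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  m <- stage("presence_matrix", read_presence_tsv(config$matrix_path))
  anchors <- stage("anchors", read_anchors_tsv(config$anchors_path))
  log$stages$inputs <- list(n_samples = nrow(m), n_transcripts = ncol(m),
                            n_viruses = length(anchors))

  orf_lengths <- setNames(numeric(0), character(0))
  if (!is.null(config$fasta_path)) {
    seqs <- stage("orf_lengths", read_fasta(config$fasta_path))
    orf_lengths <- stage("orf_lengths",
                         max_orf_lengths(seqs, mode = config$orf_mode))
    log$stages$orf <- list(status = "run", n_sequences = length(seqs))
  } else {
    log$stages$orf <- list(status = "skipped",
                           reason = "no transcript FASTA supplied")
  }

  results$candidates <- list()
  for (v in names(anchors)) {
    cand <- stage("screen",
                  screen_candidates(m, anchors[[v]], orf_lengths,
                                    config$screen))
    out <- cand
    out$v_co <- sprintf("%.4f", out$v_co)
    out$t_co <- ifelse(is.na(cand$t_co), "NA", sprintf("%.4f", cand$t_co))
    write.table(out, file.path(config$out_dir,
                               sprintf("candidates_%s.tsv", v)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    results$candidates[[v]] <- cand
  }
  log$stages$screen <- list(status = "run",
                            n_candidates = sum(vapply(results$candidates,
                                                      nrow, integer(1))))

  if (!is.null(config$alignment_path)) {
    aln <- stage("distances", read_fasta(config$alignment_path))
    D <- stage("distances", distance_matrix(aln, config$distance_policy))
    write_distance_tsv(D, file.path(config$out_dir, "distance_matrix.tsv"))
    results$distances <- D
    if (!is.null(config$groups_path)) {
      groups <- stage("group_means", read_groups_tsv(config$groups_path))
      gm <- stage("group_means", group_mean_distances(D, groups))
      gm$mean_pct <- format_pct(gm$mean_distance)
      write.table(gm, file.path(config$out_dir, "group_means.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      results$group_means <- gm
      log$stages$distances <- list(status = "run", n_sequences = length(aln),
                                   n_groups = length(unique(groups$group)))
    } else {
      log$stages$distances <- list(status = "matrix_only",
                                   n_sequences = length(aln))
    }
  } else {
    log$stages$distances <- list(status = "skipped",
                                 reason = "no alignment supplied")
  }

  if (!is.null(config$abundance_path)) {
    tab <- stage("correlation", read_abundance_tsv(config$abundance_path))
    fit <- stage("correlation", correlate_abundance(tab))
    jsonlite::write_json(
      list(slope = fit$slope, intercept = fit$intercept, r = fit$r,
           p = fit$p, n = fit$n),
      file.path(config$out_dir, "regression.json"),
      auto_unbox = TRUE, digits = NA)
    results$regression <- fit
    log$stages$correlation <- list(status = "run", n = fit$n)
  } else {
    log$stages$correlation <- list(status = "skipped",
                                   reason = "no abundance table supplied")
  }

  jsonlite::write_json(log, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(results = results, report = log))
}
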