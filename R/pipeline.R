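#' Read a sample manifest
#'
#' Tab-separated with header columns `sample_id`, `group_id`,
#' `alignment_path`. Sample ids must be unique; every group has at least one
#' sample by construction.
#'
#' @param path Manifest path.
#' @param base_dir Directory against which relative alignment paths are
#'   resolved (default: the manifest's directory).
#' @return data.frame with the three columns.
#' @export
read_manifest <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) stop("manifest does not exist: ", path, call. = FALSE)
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group_id", "alignment_path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(m$sample_id[duplicated(m$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicate sample_id in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rel <- !grepl("^/", m$alignment_path)
  m$alignment_path[rel] <- file.path(base_dir, m$alignment_path[rel])
  m[, need]
}

#' Assemble and validate a pipeline configuration
#'
#' @param reference_fasta FASTA with construct (and decoy) sequences.
#' @param manifest TSV manifest (see [read_manifest()]).
#' @param features Optional BED of construct features.
#' @param construct_ids Ids to quantify; default every sequence in the FASTA
#'   except any whose id contains `"decoy"`.
#' @param convention Strandedness convention (see [strand_rule()]).
#' @param include_duplicates,min_mapq Alignment filters
#'   (see [read_alignments()]).
#' @param baseline_feature Feature name used as retention-ratio baseline
#'   (default `"upstream_pA"` when present).
#' @param outdir Output directory; created if needed.
#' @param plots Write coverage plots (PNG) per group and construct.
#' @return A validated `run_config` list.
#' @export
run_config <- function(reference_fasta, manifest, features = NULL,
                       construct_ids = NULL,
                       convention = c("reverse", "forward"),
                       include_duplicates = TRUE, min_mapq = 0L,
                       baseline_feature = "upstream_pA",
                       outdir = "strandquant_out", plots = TRUE) {
  convention <- match.arg(convention)
  for (f in c(reference_fasta, manifest, features)) {
    if (!is.null(f) && !file.exists(f)) {
      stop("configured path does not exist: ", f, call. = FALSE)
    }
  }
  cfg <- list(reference_fasta = reference_fasta, manifest = manifest,
              features = features, construct_ids = construct_ids,
              convention = convention,
              include_duplicates = include_duplicates,
              min_mapq = as.integer(min_mapq),
              baseline_feature = baseline_feature,
              outdir = outdir, plots = plots)
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  rel <- function(p) {
    if (is.null(p) || grepl("^/", p)) p else file.path(dirname(path), p)
  }
  do.call(run_config, c(
    list(reference_fasta = rel(y$reference_fasta),
         manifest = rel(y$manifest), features = rel(y$features)),
    y[setdiff(names(y), c("reference_fasta", "manifest", "features"))]
  ))
}

#' Run the full quantification pipeline
#'
#' For every sample in the manifest: read the construct-restricted
#' alignments, count sense/antisense per position, normalise. For every
#' (group, construct): integrate across samples, write the profile and
#' per-feature region metrics, and optionally plot. Alignment paths are
#' validated before any computation; any stage error aborts naming the
#' stage and sample. A YAML run log records every parameter in effect and
#' the per-sample skip tallies.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `tracks` (per sample), `profiles`
#'   (per group x construct), `metrics` (data.frame), and `log_path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  refs <- read_fasta(config$reference_fasta)
  manifest <- read_manifest(config$manifest)
  missing <- manifest$alignment_path[!file.exists(manifest$alignment_path)]
  if (length(missing) > 0L) {
    stop("alignment file(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cids <- config$construct_ids
  if (is.null(cids)) cids <- grep("decoy", names(refs), value = TRUE,
                                  invert = TRUE)
  constructs <- refs[cids]
  features <- if (!is.null(config$features)) {
    read_features(config$features, references = refs)
  }
  rule <- strand_rule(config$convention)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, sample, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed for sample '", sample, "': ",
           conditionMessage(e), call. = FALSE)
    })
  }

  tracks <- list()
  norm <- list()
  skip_log <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    segs <- stage("read_alignments", sid, read_alignments(
      manifest$alignment_path[i], ref_ids = cids,
      include_duplicates = config$include_duplicates,
      min_mapq = config$min_mapq))
    tr <- stage("count", sid,
                count_sample(segs, constructs, rule, sample_id = sid))
    for (cid in names(tr)) {
      write_counts_tsv(tr[[cid]],
                       file.path(config$outdir,
                                 paste0("counts_", sid, "_", cid, ".tsv")))
    }
    tracks[[sid]] <- tr
    norm[[sid]] <- lapply(tr, normalize_track)
    skip_log[[sid]] <- list(
      flag_skipped = attr(segs, "n_flag_skipped"),
      unclassified = sum(vapply(tr, `[[`, 0L, "n_skipped_segments"))
    )
  }

  profiles <- list()
  metrics <- list()
  for (gid in unique(manifest$group_id)) {
    gsamples <- manifest$sample_id[manifest$group_id == gid]
    for (cid in cids) {
      prof <- integrate_group(lapply(norm[gsamples],
                                     function(x) x[[cid]]), gid)
      key <- paste0(gid, "_", cid)
      profiles[[key]] <- prof
      write_profile_tsv(prof,
                        file.path(config$outdir,
                                  paste0("profile_", key, ".tsv")))
      if (!is.null(features)) {
        feats <- features[features$construct_id == cid, , drop = FALSE]
        base <- feats[feats$name == config$baseline_feature, , drop = FALSE]
        base <- if (nrow(base) == 1L) base[1L, ] else NULL
        for (j in seq_len(nrow(feats))) {
          metrics[[length(metrics) + 1L]] <-
            region_metrics(prof, feats[j, ], baseline = base)
        }
        if (isTRUE(config$plots)) {
          pl <- plot_profile(prof, feats)
          ggplot2::ggsave(
            file.path(config$outdir, paste0("profile_", key, ".png")),
            pl, width = 9, height = 4, dpi = 150)
        }
      } else if (isTRUE(config$plots)) {
        ggplot2::ggsave(
          file.path(config$outdir, paste0("profile_", key, ".png")),
          plot_profile(prof), width = 9, height = 4, dpi = 150)
      }
    }
  }
  metrics_df <- if (length(metrics) > 0L) do.call(rbind, metrics) else NULL
  if (!is.null(metrics_df)) {
    utils::write.table(metrics_df,
                       file.path(config$outdir, "region_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  log_path <- file.path(config$outdir, "run_log.yaml")
  yaml::write_yaml(list(
    package_version = as.character(utils::packageVersion("strandquant")),
    parameters = list(
      convention = config$convention,
      include_duplicates = config$include_duplicates,
      min_mapq = config$min_mapq,
      construct_ids = cids,
      baseline_feature = config$baseline_feature
    ),
    samples = skip_log
  ), log_path)

  invisible(list(tracks = tracks, profiles = profiles,
                 metrics = metrics_df, log_path = log_path))
}

#' @importFrom ggplot2 .data
NULL
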