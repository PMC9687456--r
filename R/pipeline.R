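# End-to-end orchestration: simulate -> dedup -> callpeaks -> diffm6a ->
# annotate -> motifs -> integrate -> report, with a manifest capturing
# parameters, outputs and their checksums so a rerun with the same
# config and seed reproduces byte-identical tables.

#' Pipeline configuration
#'
#' Collects the per-stage parameters of [run_pipeline()]. The
#' `simulation` element is a full [simulation_config()]; every other
#' element tunes one downstream stage.
#'
#' @param simulation a [simulation_config()].
#' @param window peak-calling window width in bp.
#' @param alpha significance threshold for windows and differential
#'   records.
#' @param min_cov minimum combined window coverage to test.
#' @param max_gap maximum non-significant windows bridged when merging.
#' @param min_windows minimum significant windows per peak.
#' @param identity_threshold UMI sub-clustering identity threshold.
#' @param k motif k-mer length.
#' @param up_threshold,down_threshold expression fold-change thresholds.
#' @param dedup run the UMI deduplication stage on the simulated FASTQ
#'   (requires FASTQ emission; slow at high depth).
#' @return list of class `merip_pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            window = 20L, alpha = 0.05, min_cov = 10L,
                            max_gap = 0L, min_windows = 1L,
                            identity_threshold = 0.95, k = 5L,
                            up_threshold = 2, down_threshold = 0.5,
                            dedup = TRUE) {
  stopifnot(inherits(simulation, "merip_sim_config"))
  check_number(alpha, "alpha", min = 0, max = 1)
  check_number(identity_threshold, "identity_threshold", min = 0, max = 1)
  structure(list(simulation = simulation, window = as.integer(window),
                 alpha = alpha, min_cov = as.integer(min_cov),
                 max_gap = as.integer(max_gap),
                 min_windows = as.integer(min_windows),
                 identity_threshold = identity_threshold, k = as.integer(k),
                 up_threshold = up_threshold,
                 down_threshold = down_threshold,
                 dedup = isTRUE(dedup)),
            class = "merip_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [pipeline_config()] arguments; keys under
#' `simulation:` override [simulation_config()] arguments.
#'
#' @param path YAML file.
#' @return list of class `merip_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  y$simulation <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, y)
}

#' Run the full synthetic MeRIP-seq pipeline
#'
#' Executes the eight stages (simulate, dedup, callpeaks, diffm6a,
#' annotate, motifs, integrate, report) into `outdir`, writing standard
#' formats (FASTA/GTF/BED/FASTQ/TSV) at each step plus a
#' `manifest.json` with parameters, outputs and md5 checksums. A rerun
#' with the same configuration (and thus seed) writes byte-identical
#' tables. A stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()] (or path handled by
#'   [read_pipeline_config()]).
#' @param outdir output directory, created if needed.
#' @param annotation_gtf optional path to a GTF used at the annotate
#'   stage instead of the simulator's own annotation file.
#' @return list of class `merip_run` with `manifest`, `summary` and
#'   `outdir`, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         annotation_gtf = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "merip_pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  stages <- character()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    inform(sprintf("[meripkit] stage %s", name))
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline failed at stage '%s': %s", name,
                    conditionMessage(e)))
    })
    stages <<- c(stages, name)
    res
  }
  emit <- function(file) outputs <<- c(outputs, file)
  path <- function(file) file.path(outdir, file)

  run_stage("simulate", function() {
    sim <- simulate_merip(config$simulation, emit_fastq = config$dedup)
    state$sim <- sim
    write_genome_fasta(sim$genome, path("genome.fa")); emit("genome.fa")
    write_annotation_gtf(sim$annotation, path("annotation.gtf"))
    emit("annotation.gtf")
    for (cond in unique(sim$reads$condition)) {
      for (lib in unique(sim$reads$library)) {
        f <- sprintf("reads_%s_%s.bed", cond, lib)
        write_reads_bed(
          sim$reads %>% filter(.data$condition == cond, .data$library == lib),
          path(f), name = "gene_id")
        emit(f)
      }
    }
    readr::write_tsv(sim$truth_peaks, path("truth_peaks.tsv"))
    emit("truth_peaks.tsv")
    readr::write_tsv(sim$truth$true_de, path("truth_de.tsv"))
    emit("truth_de.tsv")
    if (!is.null(sim$fastq) && nrow(sim$fastq)) {
      for (cond in unique(sim$fastq$condition)) {
        for (lib in unique(sim$fastq$library)) {
          f <- sprintf("reads_%s_%s.fastq", cond, lib)
          write_fastq(
            sim$fastq %>% filter(.data$condition == cond,
                                 .data$library == lib),
            path(f))
          emit(f)
        }
      }
    }
  })

  run_stage("dedup", function() {
    sim <- state$sim
    if (!config$dedup || is.null(sim$fastq) || nrow(sim$fastq) == 0L) {
      rep <- tibble(condition = character(), library = character(),
                    reads_in = integer(), reads_out = integer(),
                    n_umi_clusters = integer(), n_subclusters = integer(),
                    n_rejected = integer())
    } else {
      groups <- sim$fastq %>% distinct(.data$condition, .data$library)
      rep <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
        sub <- sim$fastq %>%
          filter(.data$condition == groups$condition[i],
                 .data$library == groups$library[i])
        dd <- deduplicate(sub,
                          umi_length = config$simulation$umi_length,
                          identity_threshold = config$identity_threshold)
        r <- attr(dd, "report")
        r$condition <- groups$condition[i]
        r$library <- groups$library[i]
        r
      })
    }
    readr::write_tsv(rep, path("dedup_report.tsv")); emit("dedup_report.tsv")
    state$dedup_report <- rep
  })

  run_stage("callpeaks", function() {
    sim <- state$sim
    state$peaks <- list()
    for (cond in c("coarse", "fine")) {
      pk <- call_peaks(
        sim$reads %>% filter(.data$condition == cond),
        window = config$window, alpha = config$alpha,
        min_cov = config$min_cov, max_gap = config$max_gap,
        min_windows = config$min_windows,
        stranded = config$simulation$stranded)
      state$peaks[[cond]] <- pk
      f <- sprintf("peaks_%s.bed", cond)
      write_peaks_bed(pk$peaks, path(f)); emit(f)
    }
  })

  run_stage("diffm6a", function() {
    sim <- state$sim
    dm <- diff_m6a(state$peaks$coarse, state$peaks$fine, sim$reads,
                   alpha = config$alpha)
    state$diff <- dm
    readr::write_tsv(dm$records, path("differential_peaks.tsv"))
    emit("differential_peaks.tsv")
  })

  run_stage("annotate", function() {
    ann <- read_annotation_gtf(annotation_gtf %||% path("annotation.gtf"))
    state$annotation <- ann
    rec <- assign_peaks_to_genes(state$diff$records, ann)
    state$diff$records <- rec
    readr::write_tsv(rec, path("differential_peaks_annotated.tsv"))
    emit("differential_peaks_annotated.tsv")
    rd <- region_distribution(
      rec %>% filter(.data$class != "ns"), ann)
    readr::write_tsv(as_tibble(rd), path("region_distribution.tsv"))
    emit("region_distribution.tsv")
    prof <- metagene_profile(state$sim$reads, ann, anchor = "stop_codon",
                             flank = 500L, bins = 25L)
    readr::write_tsv(prof, path("metagene_profile.tsv"))
    emit("metagene_profile.tsv")
  })

  run_stage("motifs", function() {
    sim <- state$sim
    pk <- state$peaks$coarse$peaks
    if (nrow(pk) == 0L) {
      res <- tibble(kmer = character(), target_hits = integer(),
                    target_fraction = double(), background_hits = integer(),
                    background_fraction = double(), p_value = double(),
                    q_value = double(), rank = integer())
      state$rrach <- NA_real_
    } else {
      seqs <- extract_peak_sequences(pk, sim$genome)
      res <- kmer_enrichment(seqs, k = config$k,
                             shuffle_seed = config$simulation$seed)
      state$rrach <- rrach_match_fraction(seqs)
    }
    state$motifs <- res
    readr::write_tsv(as_tibble(res), path("motifs.tsv")); emit("motifs.tsv")
  })

  run_stage("integrate", function() {
    sim <- state$sim
    ann <- state$annotation
    expr <- quantify_expression(sim$reads, ann) %>%
      call_de(config$up_threshold, config$down_threshold)
    state$expression <- expr
    readr::write_tsv(as_tibble(expr), path("expression.tsv"))
    emit("expression.tsv")
    genes <- summarize_differential(state$diff$records)
    up_m6a <- genes$genes$gene_id[genes$genes$class == "up"]
    spec_m6a <- genes$genes$gene_id[genes$genes$class %in%
                                      c("coarse_specific", "fine_specific")]
    ov <- overlap_analysis(up_m6a, spec_m6a,
                           expr$gene_id[expr$de_class == "up"],
                           expr$gene_id[expr$de_class == "down"])
    state$overlap <- ov
    readr::write_tsv(as_tibble(ov), path("overlap_analysis.tsv"))
    emit("overlap_analysis.tsv")
    state$diff_summary <- genes$summary
  })

  run_stage("report", function() {
    summary <- tibble(
      metric = c("n_genes", "n_reads", "n_peaks_coarse", "n_peaks_fine",
                 "n_diff_records", "rrach_fraction_coarse_peaks",
                 "n_de_up", "n_de_down"),
      value = c(config$simulation$n_genes, nrow(state$sim$reads),
                nrow(state$peaks$coarse$peaks),
                nrow(state$peaks$fine$peaks),
                nrow(state$diff$records),
                round(state$rrach %||% NA_real_, 4),
                sum(state$expression$de_class == "up"),
                sum(state$expression$de_class == "down")))
    readr::write_tsv(summary, path("summary.tsv")); emit("summary.tsv")
    state$summary <- summary
  })

  files <- file.path(outdir, setdiff(outputs, "manifest.json"))
  manifest <- list(
    package = "meripkit",
    version = as.character(utils::packageVersion("meripkit")),
    seed = config$simulation$seed,
    parameters = config_to_list(config),
    stages = stages,
    outputs = tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(new_merip_result(
    list(manifest = manifest, summary = state$summary, outdir = outdir),
    "merip_run"))
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$simulation <- unclass(out$simulation)
  out
}
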