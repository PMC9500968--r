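#' Pipeline configuration
#'
#' Validates and normalizes the configuration for [run_pipeline()]. A
#' configuration can be built in code or loaded from a YAML file with the
#' same field names. Domain boundaries in the configuration are 1-based
#' inclusive (the biological convention used in reports); they are
#' converted to internal coordinates on load.
#'
#' @param alignment Path to the aligned protein FASTA.
#' @param domains Named list of 1-based inclusive column ranges, e.g.
#'   `list(alpha1 = c(1, 87), alpha2 = c(88, 180))`.
#' @param output_dir Output directory (created if needed).
#' @param seed Integer seed for the bootstrap.
#' @param threshold Polymorphic-site threshold in bits (default 1).
#' @param deletion_variability Deletion policy for percent-difference
#'   matrices (default `"pairwise"`).
#' @param deletion_tree Deletion policy for tree distances (default
#'   `"complete"`).
#' @param bootstrap_replicates Bootstrap replicates (default 1000).
#' @param ref_id,ref_start Optional reference row and its 1-based start
#'   position for reference numbering and conservation auditing.
#' @param scheme Optional path to a residue-scheme TSV ([read_scheme()]);
#'   when `ref_id` is set but `scheme` is not, the built-in fish anchor
#'   octet is used.
#' @param lineages Optional path to a TSV with columns `id`, `lineage`
#'   naming the reference leaves; remaining sequences are treated as
#'   queries for [assign_lineage()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment, domains, output_dir, seed,
                            threshold = 1.0,
                            deletion_variability = "pairwise",
                            deletion_tree = "complete",
                            bootstrap_replicates = 1000L,
                            ref_id = NULL, ref_start = 1L,
                            scheme = NULL, lineages = NULL) {
  if (!file.exists(alignment)) stop_invalid("alignment file not found: ", alignment)
  if (!is.null(scheme) && !file.exists(scheme))
    stop_invalid("scheme file not found: ", scheme)
  if (!is.null(lineages) && !file.exists(lineages))
    stop_invalid("lineage table not found: ", lineages)
  if (threshold < 0) stop_invalid("threshold must be >= 0")
  if (bootstrap_replicates < 1) stop_invalid("bootstrap_replicates must be >= 1")
  seed <- as.integer(seed)
  if (is.na(seed)) stop_invalid("seed must be an integer")
  domains0 <- lapply(domains, function(d) {
    d <- as.integer(d)
    if (length(d) != 2 || d[1] < 1 || d[2] < d[1])
      stop_invalid("domains must be 1-based inclusive ranges c(first, last)")
    c(d[1] - 1L, d[2])
  })
  structure(list(alignment = alignment, domains = domains0,
                 output_dir = output_dir, seed = seed,
                 threshold = threshold,
                 deletion_variability = match.arg(deletion_variability,
                                                  c("pairwise", "complete")),
                 deletion_tree = match.arg(deletion_tree,
                                           c("complete", "pairwise")),
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 ref_id = ref_id, ref_start = as.integer(ref_start),
                 scheme = scheme, lineages = lineages),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path Path to a YAML configuration file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  y <- yaml::read_yaml(path)
  need <- c("alignment", "domains", "output_dir", "seed")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop_invalid("config missing field(s): ",
                                 paste(miss, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Run the full characterization pipeline
#'
#' Executes, per domain: the per-site variability profile with
#' polymorphic-site calls, the pairwise percent-difference matrix and its
#' summary, the Poisson-corrected distance matrix, the bootstrap-annotated
#' NJ tree, and (when a lineage table is configured) lineage assignment of
#' the query sequences; plus a whole-alignment conservation report when a
#' reference row is configured. All outputs are TSV/Newick files with
#' stable names under `output_dir`; re-running with the same configuration
#' and seed reproduces them byte for byte. Any stage error aborts the run,
#' names the stage, and removes partial outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list of written file paths by stage.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  out <- function(name) {
    p <- file.path(cfg$output_dir, name)
    written <<- c(written, p)
    p
  }
  log_lines <- c(sprintf("mhcvar %s", as.character(utils::packageVersion("mhcvar"))),
                 sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
                 sprintf("config_md5 %s", config_hash(cfg)),
                 sprintf("seed %d", cfg$seed))
  stage <- "load"
  files <- list()
  tryCatch({
    aln <- read_alignment(cfg$alignment, domains = cfg$domains)
    rmap <- NULL
    if (!is.null(cfg$ref_id))
      rmap <- build_reference_map(aln, cfg$ref_id, cfg$ref_start)

    for (dom in names(cfg$domains)) {
      stage <- paste0("variability:", dom)
      t0 <- proc.time()[["elapsed"]]
      prof <- profile_alignment(aln, dom, threshold = cfg$threshold,
                                ref_map = rmap)
      p <- out(sprintf("variability_%s.tsv", dom))
      write_tsv_num(prof, p,
                    footer = sprintf("# polymorphic sites (V > %s): %d",
                                     format(cfg$threshold),
                                     attr(prof, "n_polymorphic")))
      files$variability[[dom]] <- p

      pm <- pairwise_difference_matrix(aln, dom,
                                       deletion = cfg$deletion_variability)
      s <- summarize_differences(pm)
      p <- out(sprintf("percent_difference_%s.tsv", dom))
      write_matrix_tsv(pm, p)
      files$percent[[dom]] <- p
      p <- out(sprintf("percent_summary_%s.tsv", dom))
      writeLines(c("stat\tvalue",
                   sprintf("min\t%.2f", s$min), sprintf("max\t%.2f", s$max),
                   sprintf("mean\t%.2f", s$mean), sprintf("sem\t%.2f", s$sem),
                   sprintf("n_pairs\t%d", s$n_pairs)), p)
      files$summary[[dom]] <- p
      log_lines <- c(log_lines, sprintf("stage %s done in %.2fs", stage,
                                        proc.time()[["elapsed"]] - t0))

      stage <- paste0("tree:", dom)
      t0 <- proc.time()[["elapsed"]]
      dm <- poisson_distance(p_distance_matrix(aln, dom,
                                               deletion = cfg$deletion_tree))
      p <- out(sprintf("poisson_distance_%s.tsv", dom))
      write_matrix_tsv(dm, p)
      files$distance[[dom]] <- p
      tree <- bootstrap_support(aln, replicates = cfg$bootstrap_replicates,
                                seed = cfg$seed, domain = dom,
                                deletion = cfg$deletion_tree)
      p <- out(sprintf("tree_%s.nwk", dom))
      write_newick(tree, p)
      files$tree[[dom]] <- p
      log_lines <- c(log_lines, sprintf("stage %s done in %.2fs", stage,
                                        proc.time()[["elapsed"]] - t0))

      if (!is.null(cfg$lineages)) {
        stage <- paste0("lineage:", dom)
        reftab <- utils::read.delim(cfg$lineages, stringsAsFactors = FALSE)
        refs <- stats::setNames(reftab$lineage, reftab$id)
        queries <- setdiff(names(aln$seqs), names(refs))
        calls <- assign_lineage(tree, refs, queries)
        p <- out(sprintf("lineage_%s.tsv", dom))
        write_tsv_num(calls, p)
        files$lineage[[dom]] <- p
      }
    }

    if (!is.null(cfg$ref_id)) {
      stage <- "conservation"
      scheme <- if (is.null(cfg$scheme)) anchor_scheme("fish")
                else read_scheme(cfg$scheme)
      rep <- check_residues(aln, rmap, scheme)
      p <- out("conservation_per_site.tsv")
      write_tsv_num(rep$per_site, p)
      p2 <- out("conservation_per_seq.tsv")
      write_tsv_num(rep$per_seq, p2,
                    footer = sprintf("# non-anchor substitutions: %d",
                                     rep$n_substitutions))
      files$conservation <- c(p, p2)
    }

    stage <- "log"
    logp <- file.path(cfg$output_dir, "run_log.txt")
    writeLines(log_lines, logp)
    files$log <- logp
  }, error = function(e) {
    unlink(written)
    stop2("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  invisible(files)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"),
             tmp)
  unname(tools::md5sum(tmp))
}

# stable numeric formatting so identical runs give identical bytes
write_tsv_num <- function(df, path, footer = NULL) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
      df[[j]] <- sprintf("%.6f", df[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(footer)) writeLines(footer, con)
  invisible(path)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), round(unclass(m), 6), check.names = FALSE)
  write_tsv_num(df, path)
}
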