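#' Run the full synthetic-study pipeline
#'
#' Config-driven end-to-end run: simulate an HS study, genome-scan the
#' focal phenotypes (plus the conditional scan of each focal phenotype on
#' its partner), compute RMIP profiles and call QTLs, build the Sorensen
#' similarity matrix and phenotype tree, and run the phenome-wide
#' correlation screen.  All outputs are plain text (CSV/TSV/Newick) in
#' `output_dir`, and a JSON manifest records parameters, seeds, package
#' version and MD5 checksums of every output, so identical configs give
#' identical checksums.
#'
#' @param config a list, or path to a YAML file, with (all optional)
#'   blocks `seed`, `output_dir`, `simulate` (arguments of [hs_config()]
#'   plus `n_phenotypes` for [default_architecture()]), `inputs`
#'   (`phenotype_file`, `trait_set_file` overriding the simulated
#'   phenotype table), `scan` (`focal`: character vector), `rmip` (`B`,
#'   `resample_fraction`, `entry_logp`, `window_mb`, `rmip_threshold`,
#'   `phenotypes`), `pleiotropy` (`linkage`, `method`,
#'   `group_by_trait_set`), `screen` (`focal`, `method`, `alpha`).
#' @param output_dir overrides `config$output_dir`.
#' @return the manifest (a list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- output_dir %||% config$output_dir %||%
    stop("no output_dir given", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  files <- character(0)
  add_file <- function(path) files[[basename(path)]] <<- path

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- simulate ------------------------------------------------------
  study <- run_stage("simulate", {
    sc <- config$simulate %||% list()
    chroms <- sc$chromosomes
    if (!is.null(chroms)) chroms <- unlist(chroms)
    chroms <- chroms %||% c(`1` = 100, `2` = 100, `3` = 100,
                            `4` = 100, `5` = 100)
    arch <- default_architecture(
      n_phenotypes = sc$n_phenotypes %||% 16,
      chromosomes = tibble::tibble(chrom = names(chroms),
                                   length = unname(chroms)))
    cfg <- hs_config(
      n_individuals = sc$n_individuals %||% 700,
      generations = sc$generations %||% 50,
      chromosomes = chroms,
      marker_spacing = sc$marker_spacing %||% 1,
      qtl_spec = arch$qtl_spec,
      polygenic_h2 = sc$polygenic_h2 %||% 0.1,
      missing_rate = sc$missing_rate %||% 0,
      seed = seed
    )
    simulate_hs_study(cfg, trait_sets = arch$trait_sets)
  })
  pheno <- study$phenotypes
  trait_sets <- attr(pheno, "trait_sets")

  run_stage("inputs", {
    if (!is.null(config$inputs$phenotype_file)) {
      pf <- config$inputs$phenotype_file
      if (!file.exists(pf)) stop("phenotype file not found: ", pf)
      pheno <<- tibble::as_tibble(utils::read.csv(pf, check.names = FALSE))
      tf <- config$inputs$trait_set_file
      if (!is.null(tf)) {
        if (!file.exists(tf)) stop("trait-set file not found: ", tf)
        trait_sets <<- tibble::as_tibble(utils::read.csv(tf))
      }
    }
  })

  run_stage("write_simulation", {
    utils::write.table(study$map, file.path(out_dir, "marker_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.csv(pheno, file.path(out_dir, "phenotypes.csv"),
                     row.names = FALSE)
    utils::write.csv(trait_sets, file.path(out_dir, "trait_sets.csv"),
                     row.names = FALSE)
    add_file(file.path(out_dir, "marker_map.tsv"))
    add_file(file.path(out_dir, "phenotypes.csv"))
    add_file(file.path(out_dir, "trait_sets.csv"))
  })

  pheno_names <- setdiff(names(pheno), "individual")
  focal <- config$scan$focal %||% pheno_names[seq_len(min(2, length(pheno_names)))]

  # ---- scans ---------------------------------------------------------
  run_stage("scan", {
    for (p in focal) {
      sc <- genome_scan(pheno, study$dosage, p)
      f <- file.path(out_dir, paste0("scan_", p, ".tsv"))
      utils::write.table(format_scan(sc), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_file(f)
    }
    if (length(focal) >= 2) {
      cs <- conditional_scan(pheno, study$dosage, focal[1], focal[2])
      f <- file.path(out_dir,
                     paste0("scan_", focal[1], "_given_", focal[2], ".tsv"))
      utils::write.table(format_scan(cs), f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      add_file(f)
    }
  })

  # ---- model search --------------------------------------------------
  rp <- config$rmip %||% list()
  rmip_phenos <- rp$phenotypes %||% pheno_names
  qtl_tables <- run_stage("rmip", {
    purrr::map(stats::setNames(rmip_phenos, rmip_phenos), function(p) {
      prof <- rmip(pheno, study$dosage, p,
                   B = rp$B %||% 100,
                   resample_fraction = rp$resample_fraction %||% 0.8,
                   entry_logp = rp$entry_logp %||% hs_entry_logp_default,
                   window_mb = rp$window_mb %||% 1.5,
                   seed = seed + seed_offset[["rmip"]] + match(p, rmip_phenos))
      call_qtls(prof, rmip_threshold = rp$rmip_threshold %||% 0.25)
    })
  })
  qtls <- dplyr::bind_rows(qtl_tables)
  run_stage("qtl_table", {
    f <- file.path(out_dir, "qtl_table.tsv")
    utils::write.table(qtls, f, sep = "\t", quote = FALSE, row.names = FALSE)
    add_file(f)
  })

  # ---- pleiotropy ----------------------------------------------------
  run_stage("pleiotropy", {
    pl <- config$pleiotropy %||% list()
    qt <- qtls
    items <- rmip_phenos
    if (isTRUE(pl$group_by_trait_set %||% FALSE)) {
      qt <- group_trait_sets(qtls, trait_sets)
      items <- unique(trait_sets$trait_set[trait_sets$phenotype %in%
                                             rmip_phenos])
    }
    S <- similarity_matrix(qt, method = pl$method %||% "length",
                           phenotypes = items)
    f <- file.path(out_dir, "similarity.csv")
    utils::write.csv(as.data.frame(unclass(S)), f)
    add_file(f)
    if (nrow(S) >= 3) {
      tr <- cluster_tree(S, linkage = pl$linkage %||% "average")
      f2 <- file.path(out_dir, "tree.nwk")
      write_pheno_tree(tr, f2)
      add_file(f2)
    }
  })

  # ---- screen --------------------------------------------------------
  run_stage("screen", {
    sp <- config$screen %||% list()
    scr <- correlation_screen(pheno, sp$focal %||% focal[1],
                              method = sp$method %||% "spearman")
    thr <- conservative_threshold(nrow(scr), sp$alpha %||% 0.05)
    scr$above_threshold <- !scr$degenerate & !is.na(scr$logP) &
      scr$logP >= thr
    f <- file.path(out_dir, "screen.csv")
    utils::write.csv(scr, f, row.names = FALSE)
    add_file(f)
  })

  manifest <- list(
    package = "hsqtl",
    version = as.character(utils::packageVersion("hsqtl")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    checksums = as.list(tools::md5sum(unlist(files)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

format_scan <- function(sc) {
  df <- as.data.frame(sc)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  df
}
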