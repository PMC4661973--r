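#' @importFrom tools md5sum
#' @importFrom utils packageVersion
NULL

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline on an input bundle directory
#'
#' Executes the stages in dependency order — sites, scale, nmf, predict,
#' clusters, coop, link — reading the standard-format files written by
#' [writeBundle()] (or assembled by hand in the same layout) and writing one
#' TSV per stage output plus a YAML manifest of the resolved configuration,
#' input digests and output digests. Stages communicate only via files; any
#' stage failure aborts with the stage name.
#'
#' @param inputDir directory with tfs/*.bed, p65.narrowPeak (or p65.bed),
#'   dhs.bed, tss.bed, motif.bed, marks_counts.tsv, expression.tsv and
#'   optionally cgi_a.bed, cgi_b.bed, methylation.tsv.
#' @param outdir output directory (created).
#' @param config a \linkS4class{RunConfig}; its seed drives every stochastic
#'   stage.
#' @param classes site classes to factorize and model.
#' @param minClassSites minimum class size for NMF/modeling (default 50).
#' @return the manifest, invisibly (also written to manifest.yaml).
#' @export
runPipeline <- function(inputDir, outdir, config = runConfig(),
                        classes = c("prox_s1", "dist_s1", "dist_s2"),
                        minClassSites = 50) {
  need <- c("dhs.bed", "tss.bed", "motif.bed", "marks_counts.tsv",
            "expression.tsv")
  p65_file <- if (file.exists(file.path(inputDir, "p65.narrowPeak")))
    "p65.narrowPeak" else "p65.bed"
  need <- c(need, p65_file)
  missing <- need[!file.exists(file.path(inputDir, need))]
  if (length(missing))
    stop("runPipeline: missing input file(s): ",
         paste(missing, collapse = ", "))
  if (!dir.exists(file.path(inputDir, "tfs")))
    stop("runPipeline: missing input file(s): tfs/")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    writeTable(df, path)
    outputs[[name]] <<- path
    path
  }

  # --- stage: sites --------------------------------------------------------
  sites <- .stage("sites", {
    tf_files <- list.files(file.path(inputDir, "tfs"), pattern = "\\.bed$",
                           full.names = TRUE)
    if (!length(tf_files)) stop("no TF peak files under tfs/")
    tfPeaks <- lapply(tf_files, readBed)
    names(tfPeaks) <- sub("\\.bed$", "", basename(tf_files))
    p65 <- readPeaks(file.path(inputDir, p65_file), "p65")
    dhs <- readBed(file.path(inputDir, "dhs.bed"))
    s <- buildSites(tfPeaks, p65, dhs)
    tss <- readBed(file.path(inputDir, "tss.bed"))
    s <- classifySites(s, tss, readBed(file.path(inputDir, "motif.bed")),
                       config)
    cgi_a <- file.path(inputDir, "cgi_a.bed")
    meth_f <- file.path(inputDir, "methylation.tsv")
    if (file.exists(cgi_a) && file.exists(meth_f)) {
      s <- classifyCgiMethylation(
        s, readBed(cgi_a), readBed(file.path(inputDir, "cgi_b.bed")),
        readMethylation(meth_f), config)
      emit(methylationEnrichment(s), "methylation_enrichment.tsv")
    }
    emit(sitesAsDataFrame(s), "sites.tsv")
    s
  })

  # --- stage: scale --------------------------------------------------------
  marks <- .stage("scale", {
    counts <- readTable(file.path(inputDir, "marks_counts.tsv"))
    if (!all(c("site_id", "length") %in% colnames(counts)))
      stop("marks_counts.tsv needs site_id and length columns")
    cm <- as.matrix(counts[, setdiff(colnames(counts),
                                     c("site_id", "length")), drop = FALSE])
    if (!is.numeric(cm)) stop("marks_counts.tsv has non-numeric counts")
    rownames(cm) <- counts$site_id
    idx <- match(mcols(sites)$site_id, counts$site_id)
    if (anyNA(idx))
      stop("marks_counts.tsv does not cover all regulatory sites")
    m <- scaleCounts(cm[idx, , drop = FALSE], counts$length[idx], config)
    emit(data.frame(site_id = siteIDs(m), markValues(m),
                    check.names = FALSE), "marks_scaled.tsv")
    m
  })

  # --- stage: nmf ----------------------------------------------------------
  stage_vec <- mcols(sites)$stage
  fits <- .stage("nmf", {
    fits <- list()
    for (cl in classes) {
      sel <- stage_vec == cl
      if (sum(sel) < minClassSites) next
      f <- fitNMF(markValues(marks)[sel, , drop = FALSE],
                  k = config@nmfRank, seed = config@seed + 101,
                  siteClass = cl, config = config)
      emit(data.frame(code = rownames(codes(f)), codes(f),
                      check.names = FALSE),
           paste0("codes_", cl, ".tsv"))
      emit(data.frame(site_id = rownames(f@W), codeWeights(f),
                      check.names = FALSE),
           paste0("weights_", cl, ".tsv"))
      fits[[cl]] <- f
    }
    if (!length(fits)) stop("no site class large enough to factorize")
    fits
  })

  # --- stage: predict ------------------------------------------------------
  .stage("predict", {
    reports <- list()
    for (cl in names(fits)) {
      sel <- stage_vec == cl
      y <- mcols(sites)$p65[sel]
      if (length(unique(y)) < 2) next
      wz <- as.matrix(codeWeights(fits[[cl]])[,
        paste0(rownames(codes(fits[[cl]])), "_z"), drop = FALSE])
      colnames(wz) <- rownames(codes(fits[[cl]]))
      X <- cbind(wz, mot = as.numeric(mcols(sites)$motif[sel]))
      r <- fitLogistic(X, y, seed = config@seed + 202, config = config)
      reports[[cl]] <- data.frame(
        class = cl, penalty = r@penalty, C = r@C, p_c = r@pc,
        auc_test = aucTest(r), mcc_test = mccTest(r),
        t(modelSlopes(r)), check.names = FALSE)
    }
    if (!length(reports)) stop("no class with both outcome labels")
    emit(do.call(rbind, reports), "model_reports.tsv")
  })

  # --- stage: clusters -----------------------------------------------------
  occ_t <- occupancyTable(sites)
  .stage("clusters", {
    emit(tgcSearch(occ_t, "dist_s2", config = config), "clusters_tgc.tsv")
    emit(tnrSearch(occ_t, config = config), "clusters_tnr.tsv")
  })

  # --- stage: coop ---------------------------------------------------------
  .stage("coop", {
    cm <- cooperativityMatrix(occ_t, "dist_s2", config = config)
    for (nm in names(cm))
      emit(data.frame(tf = rownames(cm[[nm]]), cm[[nm]],
                      check.names = FALSE),
           paste0("coop_", nm, ".tsv"))
  })

  # --- stage: link ---------------------------------------------------------
  .stage("link", {
    tss <- readBed(file.path(inputDir, "tss.bed"))
    links <- linkSites(tss, sites, config)
    emit(links, "links.tsv")
    expr <- readTable(file.path(inputDir, "expression.tsv"))
    upreg <- upregulationByOccupancy(links, expr, config)
    emit(upreg$byOccupancy, "upregulation_by_occupancy.tsv")
    emit(upreg$contrasts, "upregulation_contrasts.tsv")
  })

  input_files <- list.files(inputDir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package = "kbcistrome",
    version = as.character(packageVersion("kbcistrome")),
    seed = config@seed,
    config = lapply(configAsList(config), function(x)
      if (length(x) > 1) as.list(x) else x),
    inputs = as.list(md5sum(input_files)),
    outputs = as.list(md5sum(unlist(outputs))))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}
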