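# Pipeline orchestration: run every analysis stage from a config and
# write plain TSV/JSON reports, including per-IH-region "passport"
# records.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full IH chromatin analysis pipeline
#'
#' Executes map processing (gap fill, domain merge), domain topology
#' (contacts, border/internal malachite), per-region composition,
#' track overlap + shuffle enrichment tests, expression summaries and
#' replication-timing profiles, writing TSV outputs plus a JSON run log
#' (seed, iterations, every ambiguity-resolving flag) to the output
#' directory. Any stage failure aborts with the stage name.
#'
#' @param config named list (or path to a YAML/JSON file) with entries:
#'   \describe{
#'     \item{map, chromSizes}{fragment map BED and sizes TSV (required).}
#'     \item{regions}{IH regions BED4 (required).}
#'     \item{tracks}{named list of annotation track BEDs.}
#'     \item{partitions}{named list of partition BED4s.}
#'     \item{transcripts}{transcript TSV (manifest at
#'       \code{<path>.manifest} if present).}
#'     \item{probes, peaks}{scored BED files.}
#'     \item{maxGap}{gap-fill threshold (default 400).}
#'     \item{gapMode, maxSpan}{contact-matrix mode (default opaque).}
#'     \item{minOverlap}{region membership threshold (default 1).}
#'     \item{includeGaps}{composition over all five labels (default
#'       TRUE).}
#'     \item{shuffle}{list(M, seed, statistic); see [shuffleConfig()].}
#'   }
#' @param outDir output directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   paths written.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (f in c("map", "chromSizes", "regions"))
    if (is.null(config[[f]]))
      stop("config is missing required entry '", f, "'")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(
    list(maxGap = 400, gapMode = "opaque", maxSpan = Inf,
         minOverlap = 1, includeGaps = TRUE,
         shuffle = list(M = 10000, seed = 1L, statistic = "length")),
    config)
  sc <- do.call(shuffleConfig, cfg$shuffle)
  out <- list(paths = list())
  p <- function(f) file.path(outDir, f)

  map <- .stage("read_map",
                readStateMap(cfg$map, chromSizes = cfg$chromSizes))
  map <- .stage("fill_gaps", fillGaps(map, maxGap = cfg$maxGap))
  map <- .stage("merge_domains", mergeDomains(map))
  out$map <- map
  out$paths$domains <- writeDomains(map, p("domains.bed"))
  regions <- .stage("read_regions",
                    readRegions(cfg$regions,
                                seqinfo = seqinfo(stateFragments(map))))
  out$regions <- regions

  comp <- .stage("composition",
                 stateComposition(map, regions,
                                  includeGaps = cfg$includeGaps,
                                  minOverlap = cfg$minOverlap))
  write.table(comp, p("composition_ih.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  out$composition <- comp
  compG <- stateComposition(map, NULL, includeGaps = cfg$includeGaps)
  write.table(compG, p("composition_genome.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  cm <- .stage("contacts",
               contactMatrix(map, gapMode = cfg$gapMode,
                             maxSpan = cfg$maxSpan))
  write.table(cbind(state = rownames(cm), as.data.frame(cm)),
              p("contact_matrix.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  out$contacts <- cm

  mal <- .stage("malachite_labels", classifyMalachite(map, regions))
  out$malachite <- mal
  out$paths$malachite <- .writeBed(
    mal, p("malachite_labels.bed"),
    extra = data.frame(label = mal$label, region = mal$region))

  dm <- chromatinDomains(map)
  genomeLen <- sum(as.numeric(chromLengths(map)))
  shuffleRows <- list()
  ratioRows <- list()
  if (!is.null(cfg$tracks)) {
    tracks <- lapply(cfg$tracks, readTrack,
                     seqinfo = seqinfo(stateFragments(map)))
    for (tn in names(tracks)) {
      for (st in chromatinStates()) {
        q <- dm[dm$state == st]
        if (!length(q)) next
        res <- .stage(paste0("shuffle_", tn),
                      genomeWideTest(q, tracks[[tn]],
                                     chromLengths = chromLengths(map),
                                     M = sc$M, statistic = sc$statistic,
                                     seed = sc$seed))
        row <- as.data.frame(res)
        row$track <- tn; row$state <- st
        shuffleRows[[paste(tn, st)]] <- row
        dr <- densityRatio(q, tracks[[tn]], nullMean = res@nullMean)
        ratioRows[[paste(tn, st)]] <-
          data.frame(track = tn, state = st,
                     observed = dr$observed, expected = dr$expected,
                     ratio = dr$ratio)
      }
    }
    out$shuffle <- do.call(rbind, shuffleRows)
    write.table(out$shuffle, p("shuffle_tests.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$densityRatios <- do.call(rbind, ratioRows)
    write.table(out$densityRatios, p("density_ratios.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$tracks <- tracks
  }

  if (!is.null(cfg$partitions)) {
    profRows <- list()
    for (pn in names(cfg$partitions)) {
      part <- readPartition(cfg$partitions[[pn]],
                            seqinfo = seqinfo(stateFragments(map)))
      for (st in chromatinStates()) {
        q <- dm[dm$state == st]
        if (!length(q)) next
        pr <- overlapProfile(q, part)
        pr$partition <- pn; pr$state <- st
        profRows[[paste(pn, st)]] <- pr
      }
    }
    out$overlapProfiles <- do.call(rbind, profRows)
    write.table(out$overlapProfiles, p("overlap_profiles.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(cfg$transcripts)) {
    mfPath <- paste0(cfg$transcripts, ".manifest")
    se <- .stage("expression_read",
                 readTranscripts(cfg$transcripts,
                                 manifest = if (file.exists(mfPath))
                                   mfPath else NULL))
    cls <- .stage("expression_assign",
                  assignTssClass(se, map, malachiteLabels = mal))
    es <- .stage("expression_summary", expressionSummary(se, cls))
    write.table(es, p("expression_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    breadth <- data.frame(
      transcript_id = SummarizedExperiment::rowRanges(se)$transcript_id,
      class = cls, breadth = expressionBreadth(se))
    write.table(breadth, p("expression_breadth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$expression <- es
  }

  if (!is.null(cfg$probes)) {
    probes <- .stage("probes_read",
                     readProbes(cfg$probes,
                                seqinfo = seqinfo(stateFragments(map))))
    pcls <- .stage("probes_assign", assignProbeClass(probes, map))
    hist <- .stage("probes_bin", binTimingScores(probes$score, pcls))
    write.table(hist, p("timing_histogram.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    grad <- lapply(seq_along(regions), function(i) {
      g <- borderGradient(probes, regions[i])
      data.frame(region = regions$name[i], n = g$n,
                 spearman = g$spearman, slope_per_kb = g$slopePerKb,
                 slope_se = g$slopeSE, defined = g$defined)
    })
    out$gradients <- do.call(rbind, grad)
    write.table(out$gradients, p("timing_gradients.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    out$probes <- probes
    out$probeClasses <- pcls
  }

  if (!is.null(cfg$peaks)) {
    peaks <- .stage("peaks_read",
                    readTrack(cfg$peaks,
                              seqinfo = seqinfo(stateFragments(map))))
    pd <- .stage("peak_density", peakDensityByReadCount(peaks, map))
    write.table(pd, p("peak_density.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$peakDensity <- pd
    out$peaks <- peaks
  }

  # passports for every region
  pass <- lapply(regions$name, function(nm)
    regionPassport(nm, map, regions, malachite = mal,
                   tracks = out$tracks,
                   probes = out$probes))
  names(pass) <- regions$name
  jsonlite::write_json(pass, p("passports.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  out$passports <- pass

  log <- list(package = "ihscape",
              version = as.character(packageVersion("ihscape")),
              seed = sc$seed, M = sc$M, statistic = sc$statistic,
              maxGap = cfg$maxGap, gapMode = cfg$gapMode,
              maxSpan = if (is.finite(cfg$maxSpan)) cfg$maxSpan else
                "Inf",
              minOverlap = cfg$minOverlap,
              includeGaps = cfg$includeGaps,
              timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(log, p("run_log.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out)
}

#' Per-region chromatin passport
#'
#' A structured per-IH-region record: state composition, the
#' border/internal malachite inventory, per-track overlap within the
#' region, the list of embedded aquamarine fragments with their track
#' co-occupancy (which insulator/enhancer tracks each aquamarine
#' fragment touches), and the replication-timing gradient statistics.
#'
#' @param regionName region name (must match the \code{name} column).
#' @param map a [ChromatinMap-class] with merged domains.
#' @param regions region \code{GRanges} with \code{name}.
#' @param malachite labelled malachite \code{GRanges} from
#'   [classifyMalachite()] (optional).
#' @param tracks named list of track \code{GRanges} (optional).
#' @param probes scored probe \code{GRanges} (optional).
#' @return a nested \code{list} serialisable to JSON.
#' @export
regionPassport <- function(regionName, map, regions, malachite = NULL,
                           tracks = NULL, probes = NULL) {
  i <- match(regionName, regions$name)
  if (is.na(i)) stop("unknown region name: ", regionName)
  region <- regions[i]
  comp <- stateComposition(map, region, includeGaps = TRUE)
  pass <- list(region = regionName,
               chrom = as.character(seqnames(region)),
               start = start(region) - 1L, end = end(region),
               span = as.numeric(width(region)),
               composition = comp)
  if (!is.null(malachite)) {
    m <- malachite[malachite$region == regionName]
    pass$malachite <- data.frame(
      start = start(m) - 1L, end = end(m), label = m$label)
  }
  if (!is.null(tracks)) {
    pass$trackOverlapBp <- lapply(tracks, function(tr)
      overlapLength(region, tr))
    # co-occupancy of embedded aquamarine fragments
    aqua <- clipToRegions(map, region)
    aqua <- aqua[aqua$state == "aquamarine"]
    pass$aquamarine <- lapply(seq_along(aqua), function(k) {
      frag <- aqua[k]
      hit <- names(tracks)[vapply(tracks, function(tr)
        overlapLength(frag, tr) > 0, logical(1))]
      list(start = start(frag) - 1L, end = end(frag),
           tracks = as.list(hit))
    })
    pass$nAquamarine <- length(aqua)
    pass$nAquamarineWithTrack <-
      sum(vapply(pass$aquamarine,
                 function(a) length(a$tracks) > 0, logical(1)))
  }
  if (!is.null(probes)) {
    g <- borderGradient(probes, region)
    pass$timingGradient <- list(n = g$n, spearman = g$spearman,
                                slopePerKb = g$slopePerKb,
                                slopeSE = g$slopeSE,
                                defined = g$defined)
  }
  pass
}
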