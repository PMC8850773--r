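#' Construct a simulator configuration
#'
#' See \linkS4class{SimConfig} for the meaning of every field. The defaults
#' give a deliberately small but structured dataset; [simPreset()] provides
#' the standard evaluation preset.
#'
#' @param markers Named vector of marker sequence lengths (bp).
#' @param nFamilies,generaPerFamily,speciesPerGenus Tree shape.
#' @param seqsPerSpecies Fixed count or inclusive \code{c(min, max)} range.
#' @param dFamily,dGenus,dSpecies,dIntra Per-site substitution
#'   probabilities (must decrease with rank depth).
#' @param problematic \code{data.frame(genus =, marker =)} of genera whose
#'   interspecific divergence is forced to zero (\code{marker = NA} means
#'   every marker); also accepts a character vector of genus names.
#' @param singletonFraction Fraction of species emitted with one sequence.
#' @param seed Simulation seed.
#' @return A \linkS4class{SimConfig}.
#' @export
simConfig <- function(markers = c(mk1 = 300L),
                      nFamilies = 2L, generaPerFamily = 2L,
                      speciesPerGenus = 3L, seqsPerSpecies = 5L,
                      dFamily = 0.25, dGenus = 0.10, dSpecies = 0.05,
                      dIntra = 0.005,
                      problematic = character(),
                      singletonFraction = 0, seed = 1L) {
  if (is.character(problematic)) {
    problematic <- if (length(problematic))
      data.frame(genus = problematic, marker = NA_character_,
                 stringsAsFactors = FALSE)
    else data.frame(genus = character(), marker = character(),
                    stringsAsFactors = FALSE)
  }
  new("SimConfig", markers = setNames(as.integer(markers), names(markers)),
      nFamilies = as.integer(nFamilies),
      generaPerFamily = as.integer(generaPerFamily),
      speciesPerGenus = as.integer(speciesPerGenus),
      seqsPerSpecies = as.integer(seqsPerSpecies),
      dFamily = dFamily, dGenus = dGenus, dSpecies = dSpecies,
      dIntra = dIntra, problematic = problematic,
      singletonFraction = singletonFraction, seed = as.integer(seed))
}

#' Standard simulation preset
#'
#' \code{"paper-like-mini"}: three 500-bp markers over 5 families x 3
#' genera x 4 species x 8 sequences, divergences 0.10 / 0.05 / 0.005 per
#' site at genus / species / individual level, one problematic genus
#' (\code{"Gen0101"}, collapsed on every marker), and 10\% singleton
#' species to exercise the balancing filters. Small enough for exhaustive
#' leave-one-out in minutes while preserving the barcoding-gap structure
#' real marker databases show.
#'
#' @param name Preset name (only \code{"paper-like-mini"} is defined).
#' @param seed Simulation seed.
#' @param problematic Override the preset's problematic-genus list (e.g.
#'   \code{character()} for a fully clean dataset).
#' @return A \linkS4class{SimConfig}.
#' @export
simPreset <- function(name = "paper-like-mini", seed = 1L,
                      problematic = "Gen0101") {
  if (name != "paper-like-mini") stop("unknown preset: ", name)
  simConfig(markers = c(mk1 = 500L, mk2 = 500L, mk3 = 500L),
            nFamilies = 5L, generaPerFamily = 3L, speciesPerGenus = 4L,
            seqsPerSpecies = 8L, dFamily = 0.25, dGenus = 0.10,
            dSpecies = 0.05, dIntra = 0.005,
            problematic = problematic,
            singletonFraction = 0.1, seed = seed)
}

#' Substitute sites of a sequence at a fixed per-site probability
#'
#' Every position is independently replaced, with the given probability,
#' by one of the three alternative bases (chosen uniformly). Length is
#' preserved; there are no indels. Draws come from the current RNG stream
#' (the simulator seeds it; seed explicitly when calling directly).
#'
#' @param sequence A character DNA string (ACGT).
#' @param perSiteProb Substitution probability per site, in [0, 1].
#' @return The mutated character string.
#' @export
mutateSequence <- function(sequence, perSiteProb) {
  stopifnot(perSiteProb >= 0, perSiteProb <= 1)
  if (perSiteProb == 0) return(sequence)
  bases <- c("A", "C", "G", "T")
  v <- match(strsplit(sequence, "")[[1L]], bases)
  hit <- which(stats::runif(length(v)) < perSiteProb)
  if (length(hit)) {
    # offset 1..3 from the current base, cyclically: uniform over the
    # three alternatives, never the original base
    off <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- (v[hit] - 1L + off) %% 4L + 1L
  }
  paste(bases[v], collapse = "")
}

.padNum <- function(i, width = 2L) formatC(i, width = width, flag = "0")

#' Simulate multi-marker reference sets with known structure
#'
#' For each marker: every family gets an independent uniform-random
#' ancestral sequence; genus ancestors are derived from it by
#' [mutateSequence()] at \code{dGenus}, species ancestors from the genus
#' ancestor at \code{dSpecies} (forced to 0 for problematic genera on the
#' affected markers), and individual sequences from the species ancestor
#' at \code{dIntra}. All markers share one taxonomy (a single
#' phylum/class/order, families \code{Fam01} ..., genera \code{Gen0101}
#' ..., species \code{Gen0101_sp01} ...). A fixed fraction of species is
#' emitted with exactly one sequence. Fully reproducible from the seed;
#' each marker draws from its own derived substream.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return List with elements \code{refsets} (named list of
#'   \linkS4class{ReferenceSet}, one per marker) and \code{truth}
#'   (\code{data.frame} per genus x marker: effective \code{d_species} and
#'   a \code{problematic} flag).
#' @export
simulateMarkers <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  bases <- c("A", "C", "G", "T")

  nGenera <- config@nFamilies * config@generaPerFamily
  famNames <- paste0("Fam", .padNum(seq_len(config@nFamilies)))
  genName <- function(f, g) paste0("Gen", .padNum(f), .padNum(g))
  nSpeciesTotal <- nGenera * config@speciesPerGenus

  # which species are singletons: a fixed, seed-derived draw shared by all
  # markers (taxonomy-level property, not a marker-level one)
  set.seed(.deriveSeed(config@seed, "singletons"))
  nSingle <- round(config@singletonFraction * nSpeciesTotal)
  singletonIdx <- if (nSingle > 0)
    sort(sample.int(nSpeciesTotal, nSingle)) else integer()
  # per-species sequence counts, shared across markers
  counts <- if (length(config@seqsPerSpecies) == 1L)
    rep(config@seqsPerSpecies, nSpeciesTotal)
  else
    sample(seq(config@seqsPerSpecies[1L], config@seqsPerSpecies[2L]),
           nSpeciesTotal, replace = TRUE)
  counts[singletonIdx] <- 1L

  isProblematic <- function(genus, marker) {
    p <- config@problematic
    any(p$genus == genus & (is.na(p$marker) | p$marker == marker))
  }

  refsets <- list()
  truthRows <- list()
  for (marker in names(config@markers)) {
    L <- config@markers[[marker]]
    set.seed(.deriveSeed(config@seed, paste0("marker:", marker)))
    ids <- character(); seqs <- character(); lineages <- character()
    spCounter <- 0L
    for (f in seq_len(config@nFamilies)) {
      famRoot <- paste(sample(bases, L, replace = TRUE), collapse = "")
      for (g in seq_len(config@generaPerFamily)) {
        genus <- genName(f, g)
        genusAnc <- mutateSequence(famRoot, config@dGenus)
        dSp <- if (isProblematic(genus, marker)) 0 else config@dSpecies
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          marker = marker, genus = genus, d_species = dSp,
          problematic = dSp == 0, stringsAsFactors = FALSE)
        for (s in seq_len(config@speciesPerGenus)) {
          spCounter <- spCounter + 1L
          species <- paste0(genus, "_sp", .padNum(s))
          spAnc <- mutateSequence(genusAnc, dSp)
          for (i in seq_len(counts[spCounter])) {
            ids <- c(ids, paste(marker, species, .padNum(i), sep = "_"))
            seqs <- c(seqs, mutateSequence(spAnc, config@dIntra))
            lineages <- c(lineages, formatLineage(c(
              phylum = "Phy01", class = "Cla01", order = "Ord01",
              family = famNames[f], genus = genus, species = species)))
          }
        }
      }
    }
    refsets[[marker]] <- ReferenceSet(
      marker, Biostrings::DNAStringSet(setNames(seqs, ids)),
      setNames(lineages, ids))
  }
  truth <- do.call(rbind, truthRows)
  rownames(truth) <- NULL
  list(refsets = refsets, truth = truth)
}

#' Write simulator output to FASTA + taxonomy + truth files
#'
#' @param sim Output of [simulateMarkers()].
#' @param dir Output directory (created if needed): writes
#'   \code{<marker>.fasta}, \code{<marker>.tax} and \code{truth.tsv}.
#' @return Invisibly, the directory.
#' @export
writeSimOutput <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (marker in names(sim$refsets)) {
    writeReferenceSet(sim$refsets[[marker]],
                      file.path(dir, paste0(marker, ".fasta")),
                      file.path(dir, paste0(marker, ".tax")))
  }
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
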