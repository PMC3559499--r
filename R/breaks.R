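#' Configuration for molecule-level break simulation
#'
#' Defines how single- and double-strand breaks are drawn on the ~172 kb
#' circular minichromosome. Counts per molecule come from either a fixed
#' number or a Poisson model; positions are i.i.d. uniform on the circle
#' (the radiation-induced DSB position is not sequence-specific).
#' Defaults reproduce the 50 Gy reference condition: exactly one DSB per
#' linearised molecule, Poisson(8.5) SSBs.
#'
#' @param genome_length Circle length in kb (default 172).
#' @param dsb_count_model,ssb_count_model Either
#'   `list(fixed = n)` or `list(poisson = lambda)`.
#' @param seed Integer seed for reproducible populations.
#' @return An object of class `break_config`.
#' @examples
#' break_config()
#' break_config(ssb_count_model = list(fixed = 8))
#' @export
break_config <- function(genome_length = 172,
                         dsb_count_model = list(fixed = 1),
                         ssb_count_model = list(poisson = 8.5),
                         seed = 1) {
  if (!is.numeric(genome_length) || genome_length <= 0) {
    stop("genome_length must be > 0", call. = FALSE)
  }
  check_model <- function(m, what) {
    if (!is.list(m) || length(m) != 1L ||
        !names(m) %in% c("fixed", "poisson") ||
        !is.numeric(m[[1]]) || m[[1]] < 0) {
      stop(what, " must be list(fixed = n) or list(poisson = lambda), ",
           "parameter >= 0", call. = FALSE)
    }
    if (names(m) == "fixed" && m[[1]] != round(m[[1]])) {
      stop(what, ": fixed count must be an integer", call. = FALSE)
    }
  }
  check_model(dsb_count_model, "dsb_count_model")
  check_model(ssb_count_model, "ssb_count_model")
  structure(list(genome_length = genome_length,
                 dsb_count_model = dsb_count_model,
                 ssb_count_model = ssb_count_model,
                 seed = as.integer(seed)),
            class = "break_config")
}

draw_counts <- function(model, n) {
  if (names(model) == "fixed") rep(as.integer(model[[1]]), n)
  else stats::rpois(n, model[[1]])
}

#' Simulate break induction across a molecule population
#'
#' Draws per-molecule DSB and SSB counts from the configured models and
#' places each break uniformly at random on the circular genome.
#'
#' @param n_molecules Number of molecules (>= 1).
#' @param cfg A [break_config()].
#' @return A `break_population`: list of molecules, each with
#'   `dsb_positions` and `ssb_positions` in kb, plus the config.
#' @export
induce_breaks <- function(n_molecules, cfg = break_config()) {
  stopifnot(inherits(cfg, "break_config"))
  if (!is.numeric(n_molecules) || n_molecules < 1) {
    stop("n_molecules must be >= 1", call. = FALSE)
  }
  n_molecules <- as.integer(n_molecules)
  gl <- cfg$genome_length
  mols <- with_seed(cfg$seed, {
    n_dsb <- draw_counts(cfg$dsb_count_model, n_molecules)
    n_ssb <- draw_counts(cfg$ssb_count_model, n_molecules)
    dsb_pos <- stats::runif(sum(n_dsb), 0, gl)
    ssb_pos <- stats::runif(sum(n_ssb), 0, gl)
    di <- cumsum(n_dsb); si <- cumsum(n_ssb)
    lapply(seq_len(n_molecules), function(i) {
      list(dsb_positions = dsb_pos[seq.int(di[i] - n_dsb[i] + 1,
                                           length.out = n_dsb[i])],
           ssb_positions = ssb_pos[seq.int(si[i] - n_ssb[i] + 1,
                                           length.out = n_ssb[i])])
    })
  })
  structure(list(molecules = mols, config = cfg), class = "break_population")
}

#' @export
print.break_population <- function(x, ...) {
  nd <- vapply(x$molecules, function(m) length(m$dsb_positions), 0L)
  ns <- vapply(x$molecules, function(m) length(m$ssb_positions), 0L)
  cat(sprintf("Break population: %d molecules on a %g kb circle\n",
              length(x$molecules), x$config$genome_length))
  cat(sprintf("  mean DSB/molecule = %.3g, mean SSB/molecule = %.3g\n",
              mean(nd), mean(ns)))
  invisible(x)
}

#' Classify a molecule into a model compartment
#'
#' A DSB linearises the circle; SSBs nick it. The compartment is read off
#' the break content: no breaks -> `S`; DSB only -> `L`; DSB and SSBs ->
#' `LSSB`; SSBs only -> `CSSB`.
#'
#' @param m A molecule (element of a `break_population`), i.e. a list with
#'   `dsb_positions` and `ssb_positions`.
#' @return One of `"S"`, `"L"`, `"LSSB"`, `"CSSB"`.
#' @export
classify_molecule <- function(m) {
  has_dsb <- length(m$dsb_positions) > 0L
  has_ssb <- length(m$ssb_positions) > 0L
  if (has_dsb) {
    if (has_ssb) "LSSB" else "L"
  } else {
    if (has_ssb) "CSSB" else "S"
  }
}

#' S1-nuclease fragmentation of a linearised molecule
#'
#' Opens the circle at the double-strand break and converts every
#' single-strand break into a cut (nuclease S1 cleaves the intact strand
#' opposite each nick in a linear duplex), so a molecule with n SSBs
#' yields n + 1 fragments whose lengths sum to the genome length.
#' Molecules without a DSB are not substrates for this assay (the gel
#' quantitation starts from the excised linear band).
#'
#' @param m A molecule with at least one DSB.
#' @param genome_length Circle length in kb.
#' @return Numeric vector of fragment lengths in kb.
#' @examples
#' s1_fragments(list(dsb_positions = 0, ssb_positions = c(43, 86, 129)), 172)
#' @export
s1_fragments <- function(m, genome_length = 172) {
  if (length(m$dsb_positions) == 0L) {
    stop("s1_fragments requires a linearised molecule (>= 1 DSB)",
         call. = FALSE)
  }
  d <- m$dsb_positions[1]
  cuts <- sort((m$ssb_positions - d) %% genome_length)
  diff(c(0, cuts, genome_length))
}

#' Estimate the per-molecule SSB count from a mean fragment length
#'
#' Two conventions are reported: `n_ratio = genome_length / mean_fragment`
#' (breaks-as-cuts reading, counting the DSB opening as one of the cuts)
#' and `n_frag = n_ratio - 1` (n SSBs give n + 1 fragments). The integer
#' bracket spans both conventions, and the midpoint of the two integers
#' flanking `n_ratio` summarises the usual "x to y breaks" statement: at
#' the reference values (mean fragment ~20 kb of a 172 kb molecule) this
#' gives 8 to 9 breaks, midpoint 8.5.
#'
#' @param mean_fragment Mean S1 fragment length in kb.
#' @param genome_length Molecule length in kb.
#' @return List with `n_ratio`, `n_frag`, `bracket` (integer range
#'   `c(floor(n_frag), ceiling(n_ratio))`), and `midpoint` (mean of the
#'   integers flanking `n_ratio`).
#' @examples
#' estimate_ssb_count(20, 172)
#' @export
estimate_ssb_count <- function(mean_fragment, genome_length = 172) {
  if (!is.numeric(mean_fragment) || mean_fragment <= 0) {
    stop("mean_fragment must be > 0", call. = FALSE)
  }
  if (mean_fragment > genome_length) {
    stop("mean_fragment cannot exceed genome_length", call. = FALSE)
  }
  n_ratio <- genome_length / mean_fragment
  n_frag <- n_ratio - 1
  list(n_ratio = n_ratio,
       n_frag = n_frag,
       bracket = c(floor(n_frag), ceiling(n_ratio)),
       midpoint = mean(c(floor(n_ratio), ceiling(n_ratio))))
}

#' Compartment fractions of a simulated population
#'
#' Classifies every molecule and returns the compartment fractions as a
#' [compartment_state()], bridging the molecule-level simulator to the
#' kinetic model's initial state.
#'
#' @param population A `break_population`.
#' @return A `repair_state`.
#' @export
population_fractions <- function(population) {
  stopifnot(inherits(population, "break_population"))
  if (length(population$molecules) == 0L) {
    stop("population is empty", call. = FALSE)
  }
  labels <- vapply(population$molecules, classify_molecule, "")
  tab <- table(factor(labels, levels = c("S", "L", "LSSB", "CSSB")))
  frac <- as.numeric(tab) / length(labels)
  compartment_state(S = frac[1], L = frac[2], LSSB = frac[3], CSSB = frac[4])
}

#' Export break positions as BED-like intervals
#'
#' Writes zero-length, 0-based half-open intervals on a single
#' "minichromosome" contig, one row per break, with the molecule index and
#' break type in the name column.
#'
#' @param population A `break_population`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_breaks_bed <- function(population, path) {
  stopifnot(inherits(population, "break_population"))
  rows <- do.call(rbind, lapply(seq_along(population$molecules), function(i) {
    m <- population$molecules[[i]]
    pos <- c(m$dsb_positions, m$ssb_positions)
    if (length(pos) == 0L) return(NULL)
    type <- c(rep("DSB", length(m$dsb_positions)),
              rep("SSB", length(m$ssb_positions)))
    data.frame(chrom = "minichromosome",
               start = round(pos * 1000), end = round(pos * 1000),
               name = sprintf("mol%d_%s", i, type))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
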