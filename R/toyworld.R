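# Deterministic synthetic micro-chemistry: molecules are strings over a small
# atom alphabet, reactions are junction rewrites of two reactant strings, and
# rule-based spectra are deterministic hashes of substructure counts. Each
# modality is deliberately lossy on its own (IR keeps only bigram occurrence,
# NMR local environments, MS masses with symbol collisions) so multi-source
# deduction measurably helps.

#' Configure a synthetic micro-chemistry world
#'
#' @param alphabet Ordered character vector of distinct 1-character atom
#'   symbols (default 8 symbols A-H).
#' @param atom_masses Named positive integer masses, one per symbol. The
#'   defaults contain deliberate collisions (A/D and B/F share a mass) so the
#'   mass spectrum alone does not identify a molecule.
#' @param rewrite_rules Named character vector mapping a 2-character pattern
#'   to a replacement at most as long; a reaction rewrites the pattern
#'   straddling the junction of its two concatenated reactants.
#' @param max_len Maximum molecule string length (<= 20).
#' @param null_ratio Desired null:real record count ratio (default 0.5,
#'   giving the ~2:1 real:null balance of the training corpus).
#' @param seed Integer seed; fully determines every generated record.
#' @param grid_points Named integer lengths of the spectral grids. Defaults
#'   to the standard 900/993/999; reduced worlds may shrink them.
#' @param inert_reagent Fixed inert molecule used to fill the reagent slot.
#' @param reagent_prob Fraction of records carrying the inert reagent
#'   (exercises the `">"` separator path).
#' @return An object of class `toy_world_config`.
#' @export
toy_world_config <- function(alphabet = c("A", "B", "C", "D", "E", "F", "G", "H"),
                             atom_masses = c(A = 10, B = 12, C = 14, D = 10,
                                             E = 16, F = 12, G = 18, H = 20),
                             rewrite_rules = c(AB = "C", BA = "D", CD = "A",
                                               DC = "B", EF = "G", FE = "H",
                                               GH = "E", HG = "F"),
                             max_len = 20,
                             null_ratio = 0.5,
                             seed = 1,
                             grid_points = c(IR = 900L, NMR = 993L, MS = 999L),
                             inert_reagent = "GG",
                             reagent_prob = 0.5) {
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet)) stop("alphabet symbols must be distinct")
  if (any(nchar(alphabet) != 1L)) stop("alphabet symbols must be single characters")
  if (!all(alphabet %in% names(atom_masses)))
    stop("atom_masses must name every alphabet symbol")
  if (any(atom_masses < 1)) stop("atom masses must be >= 1")
  if (max_len > 20) stop("max_len must be <= 20")
  if (length(rewrite_rules)) {
    if (is.null(names(rewrite_rules))) stop("rewrite_rules must be named pattern -> replacement")
    if (any(nchar(rewrite_rules) > nchar(names(rewrite_rules))))
      stop("rewrite replacements must not be longer than their patterns")
    symbols_used <- unique(strsplit(paste0(c(names(rewrite_rules), rewrite_rules),
                                           collapse = ""), "")[[1]])
    if (!all(symbols_used %in% alphabet))
      stop("rewrite rules use symbols outside the alphabet")
  }
  stopifnot(null_ratio >= 0, reagent_prob >= 0, reagent_prob <= 1)
  structure(
    list(alphabet = alphabet,
         atom_masses = atom_masses[alphabet],
         rewrite_rules = rewrite_rules,
         max_len = as.integer(max_len),
         null_ratio = null_ratio,
         seed = as.integer(seed),
         grid_points = c(IR = as.integer(grid_points[["IR"]]),
                         NMR = as.integer(grid_points[["NMR"]]),
                         MS = as.integer(grid_points[["MS"]])),
         inert_reagent = inert_reagent,
         reagent_prob = reagent_prob),
    class = "toy_world_config"
  )
}

# Deterministic string hashes (platform-independent; plain double arithmetic
# stays exact far below 2^53).
hash_chr <- function(s, base = 31, mod = 1000003) {
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * base + code) %% mod
  h
}

check_molecule <- function(molecule, config) {
  if (!is.character(molecule) || length(molecule) != 1L)
    stop("molecule must be a character scalar")
  if (nchar(molecule) > config$max_len)
    stop("molecule longer than max_len")
  if (nzchar(molecule)) {
    symbols <- strsplit(molecule, "")[[1]]
    bad <- setdiff(symbols, config$alphabet)
    if (length(bad))
      stop("invalid molecule: unknown symbol(s) ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# Add a peak (or fixed-width triangular bump) into an intensity vector,
# combining overlaps by maximum.
add_peak <- function(x, center, height, halfwidth = 0L) {
  n <- length(x)
  if (halfwidth == 0L) {
    if (center >= 1 && center <= n) x[center] <- max(x[center], height)
    return(x)
  }
  for (o in -halfwidth:halfwidth) {
    j <- center + o
    if (j >= 1 && j <= n) {
      frac <- 1 - abs(o) / (halfwidth + 1)
      x[j] <- max(x[j], height * frac)
    }
  }
  x
}

#' Simulate a rule-based spectrum for a toy molecule
#'
#' Deterministic, structure-correlated intensity vectors standing in for
#' physical spectra:
#' * **MS**: unit peak at the total atom mass plus lower-intensity fragment
#'   peaks at every prefix mass (positions are m/z values on a 1 m/z grid).
#' * **IR**: fixed-width triangular bumps at grid positions hashed from
#'   boundary-padded bigrams, heights scaled by occurrence count.
#' * **NMR**: peaks at positions hashed from (left neighbor, symbol, right
#'   neighbor) environments with intensity proportional to the environment's
#'   multiplicity.
#'
#' The same (molecule, modality, config) always yields a bit-identical
#' vector; non-empty molecules have maximum intensity 1.
#'
#' @param molecule Molecule string over the world's alphabet (may be empty).
#' @param modality `"IR"`, `"NMR"` or `"MS"`.
#' @param config A [toy_world_config()].
#' @return A [spectrum()].
#' @export
simulate_spectrum <- function(molecule, modality, config) {
  stopifnot(inherits(config, "toy_world_config"))
  if (!modality %in% c("IR", "NMR", "MS"))
    stop("unknown modality: ", modality)
  check_molecule(molecule, config)
  n <- config$grid_points[[modality]]
  x <- numeric(n)
  if (!nzchar(molecule))
    return(spectrum(x, modality))
  symbols <- strsplit(molecule, "")[[1]]
  k <- length(symbols)

  if (modality == "MS") {
    masses <- cumsum(config$atom_masses[symbols])
    # fixed-height fragment (prefix) peaks below the unit molecular ion
    if (k > 1) for (j in seq_len(k - 1)) x <- add_peak(x, masses[j], 0.5)
    x <- add_peak(x, masses[k], 1.0)          # molecular ion
  } else if (modality == "IR") {
    padded <- c("^", symbols, "$")
    bigrams <- paste0(padded[-length(padded)], padded[-1])
    tab <- table(bigrams)
    for (b in names(tab)) {
      center <- 1L + (hash_chr(b) %% n)
      x <- add_peak(x, center, tab[[b]], halfwidth = 2L)
    }
  } else {
    padded <- c("^", symbols, "$")
    envs <- paste0(padded[seq_len(k)], symbols, padded[3:(k + 2)])
    tab <- table(envs)
    for (e in names(tab)) {
      center <- 1L + (hash_chr(e) %% n)
      x <- add_peak(x, center, tab[[e]])      # intensity ~ multiplicity
    }
  }
  m <- max(x)
  if (m > 0) x <- x / m
  spectrum(x, modality)
}

simulate_all_spectra <- function(molecule, config) {
  list(IR = simulate_spectrum(molecule, "IR", config),
       NMR = simulate_spectrum(molecule, "NMR", config),
       MS = simulate_spectrum(molecule, "MS", config))
}

random_fragment <- function(alphabet, len) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

new_record <- function(reactants, reagent, target, is_null, config) {
  list(reactants = reactants,
       reagent = reagent,
       target = target,
       is_null = is_null,
       spectra = simulate_all_spectra(target, config))
}

reactant_key <- function(record) paste(record$reactants, collapse = ".")

#' Generate a synthetic reaction corpus
#'
#' Draws `n_real` real reactions (two reactant strings whose junction carries
#' a rewrite-rule pattern; the product is the junction rewrite), then
#' augments with null reactions -- records whose target is one of the
#' reactants, with that reactant's spectra -- built via
#' [make_null_reactions()] (so candidates whose target coincides with any
#' real product are discarded) and subsampled to approximately
#' `null_ratio * n_real`, spreading nulls across distinct reactant sets so
#' the one-to-many reactant-to-target mapping is guaranteed.
#'
#' @param config A [toy_world_config()]; its seed fully determines the
#'   output.
#' @param n_real Number of real reactions (>= 0).
#' @return List of reaction records, each with fields `reactants`, `reagent`,
#'   `target`, `is_null`, and `spectra` (IR/NMR/MS of the target).
#' @export
generate_reactions <- function(config, n_real) {
  stopifnot(inherits(config, "toy_world_config"))
  if (n_real < 0) stop("n_real must be >= 0")
  if (length(config$rewrite_rules) == 0) stop("rewrite_rules must be non-empty")
  if (n_real == 0) return(list())
  with_local_seed(config$seed, {
    patterns <- names(config$rewrite_rules)
    half <- max(3L, (config$max_len - 1L) %/% 2L)
    reals <- vector("list", n_real)
    for (i in seq_len(n_real)) {
      repeat {
        ri <- sample(length(patterns), 1L)
        pat <- patterns[ri]
        repl <- config$rewrite_rules[[ri]]
        l1 <- sample(2:half, 1L)
        l2 <- sample(2:half, 1L)
        r1 <- paste0(random_fragment(config$alphabet, l1 - 1L), substr(pat, 1, 1))
        r2 <- paste0(substr(pat, 2, 2), random_fragment(config$alphabet, l2 - 1L))
        product <- paste0(substr(r1, 1, l1 - 1L), repl, substr(r2, 2, l2))
        if (nchar(product) <= config$max_len && !(product %in% c(r1, r2)))
          break
      }
      reagent <- if (runif(1) < config$reagent_prob) config$inert_reagent else NULL
      reals[[i]] <- new_record(c(r1, r2), reagent, product, FALSE, config)
    }
    candidates <- make_null_reactions(reals, config)
    n_null <- round(config$null_ratio * n_real)
    nulls <- list()
    if (n_null > 0 && length(candidates) > 0) {
      keys <- vapply(candidates, reactant_key, character(1))
      groups <- split(seq_along(candidates), keys)
      groups <- groups[sample(length(groups))]
      first <- vapply(groups, `[`, integer(1), 1L)
      rest <- unlist(lapply(groups, `[`, -1L), use.names = FALSE)
      take <- c(first, rest)[seq_len(min(n_null, length(candidates)))]
      nulls <- candidates[take]
    }
    c(reals, nulls)
  })
}
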