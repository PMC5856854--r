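# run code under a private RNG stream without disturbing the caller's state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic screening simulator
#'
#' Describes the statistical situation the fingerprint method is built for: a
#' set of reference complexes sharing a "true" pattern of favourable
#' interactions, active poses that largely reproduce that pattern, and decoy
#' poses whose favourable interactions fall elsewhere in the site.
#'
#' Defaults describe one synthetic screening campaign: a 30-atom cavity with
#' a 20-element true interaction pattern (of 240 fingerprint elements), 10
#' reference complexes each showing a given true interaction with probability
#' 0.7 — conserved key contacts present in most but not all crystal
#' structures — 50 actives realizing true interactions with probability 0.8,
#' 50 decoys with a random same-sized pattern, and a 2% per-element rate of
#' spurious repulsive contacts.
#'
#' @param n_atoms Number of binding-site atoms (fingerprint rows).
#' @param n_references Number of reference complexes.
#' @param n_true_elements Size of the shared favourable pattern; at most
#'   `8 * n_atoms`.
#' @param presence_prob Per-reference probability that a true element is
#'   favourable in that reference, in `(0, 1]`.
#' @param strength_scale Magnitude scale (score units) of favourable values;
#'   magnitudes are half-normal with this scale. The published score ignores
#'   magnitudes, so this only exercises I/O and sign handling.
#' @param noise_prob Per-element probability of a spurious unfavourable
#'   (repulsive, positive after normalization) value, in `[0, 1)`.
#' @param n_actives,n_decoys Pose counts for the labelled screen.
#' @param active_overlap Probability an active pose realizes each true
#'   element, in `[0, 1]`.
#' @param seed Integer seed; every generator output is a deterministic
#'   function of the config including this seed.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_atoms = 30L, n_references = 10L,
                              n_true_elements = 20L, presence_prob = 0.7,
                              strength_scale = 2, noise_prob = 0.02,
                              n_actives = 50L, n_decoys = 50L,
                              active_overlap = 0.8, seed = 1L) {
  cfg <- list(n_atoms = as.integer(n_atoms),
              n_references = as.integer(n_references),
              n_true_elements = as.integer(n_true_elements),
              presence_prob = as.numeric(presence_prob),
              strength_scale = as.numeric(strength_scale),
              noise_prob = as.numeric(noise_prob),
              n_actives = as.integer(n_actives),
              n_decoys = as.integer(n_decoys),
              active_overlap = as.numeric(active_overlap),
              seed = as.integer(seed))
  stopifnot(cfg$n_atoms >= 1L, cfg$n_references >= 1L,
            cfg$n_true_elements >= 1L,
            cfg$n_true_elements <= 8L * cfg$n_atoms,
            cfg$presence_prob > 0, cfg$presence_prob <= 1,
            cfg$strength_scale > 0,
            cfg$noise_prob >= 0, cfg$noise_prob < 1,
            cfg$n_actives >= 0L, cfg$n_decoys >= 0L,
            cfg$active_overlap >= 0, cfg$active_overlap <= 1,
            !is.na(cfg$seed))
  structure(cfg, class = "simulation_config")
}

#' Read / write a flat key:value simulation config file
#'
#' One `key: value` pair per line; keys are the arguments of
#' [simulation_config()], unknown keys are an error, omitted keys take their
#' defaults.
#'
#' @param path File path.
#' @return `read_simulation_config()` returns a [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  lines <- .read_tsv_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([A-Za-z_]+) *: *(.+)$", ln))[[1]]
    if (length(kv) != 3L)
      stop(path, ": malformed config line: ", ln, call. = FALSE)
    args[[kv[2]]] <- as.numeric(kv[3])
  }
  known <- names(formals(simulation_config))
  bad <- setdiff(names(args), known)
  if (length(bad))
    stop(path, ": unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(simulation_config, args)
}

#' @rdname read_simulation_config
#' @param cfg A [simulation_config()].
#' @export
write_simulation_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  writeLines(sprintf("%s: %s", names(cfg),
                     vapply(cfg, .format_num, character(1))), path)
  invisible(path)
}

#' Synthetic cavity atom list
#'
#' Builds a plausible binding-site atom list: chain A, consecutive residue
#' numbers, side-chain-like atom names cycling per residue.
#'
#' @param n_atoms Number of atoms.
#' @return A [cavity_atoms()] object.
#' @export
synthetic_cavity <- function(n_atoms) {
  names_cycle <- c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2")
  cavity_atoms(atom_keys(chain = "A",
                         resnum = ((seq_len(n_atoms) - 1L) %/% length(names_cycle)) + 1L,
                         icode = "",
                         atom_name = names_cycle[((seq_len(n_atoms) - 1L) %% length(names_cycle)) + 1L]))
}

# elements eligible for favourable interactions: all terms except
# PLP.S(repulsive), which is repulsive by construction
.favourable_universe <- function(n_atoms) {
  expand.grid(atom = seq_len(n_atoms), term = 1:7)
}

#' Draw the true favourable-interaction pattern
#'
#' Samples the shared pattern of `n_true_elements` (atom, term) elements that
#' references and actives realize. The repulsive term never hosts a
#' favourable interaction, so the pattern is drawn from the other seven
#' columns. Deterministic given the config (its seed included).
#'
#' @param cfg A [simulation_config()].
#' @return Integer matrix with columns `atom`, `term`.
#' @export
sample_true_pattern <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  univ <- .favourable_universe(cfg$n_atoms)
  stopifnot(cfg$n_true_elements <= nrow(univ))
  with_local_seed(cfg$seed, {
    pick <- sample.int(nrow(univ), cfg$n_true_elements)
    m <- as.matrix(univ[sort(pick), ])
    dimnames(m) <- list(NULL, c("atom", "term"))
    m
  })
}

# raw-convention favourable value at term j: the exporter reports the three
# ChemScore terms positive-is-favourable, the PLP terms negative
.raw_favourable <- function(term, magnitude) {
  ifelse(term %in% .sign_reversed_terms, magnitude, -magnitude)
}
.raw_unfavourable <- function(term, magnitude) {
  ifelse(term %in% .sign_reversed_terms, -magnitude, magnitude)
}

# one raw score table: favourable at `elements` (matrix atom/term), spurious
# repulsive noise elsewhere with prob noise_prob
.random_table <- function(cfg, elements, source_id) {
  v <- matrix(0, cfg$n_atoms, 8L)
  if (nrow(elements) > 0) {
    mag <- abs(stats::rnorm(nrow(elements))) * cfg$strength_scale
    v[elements] <- .raw_favourable(elements[, 2L], mag)
  }
  if (cfg$noise_prob > 0) {
    free <- which(v == 0)
    hit <- free[stats::runif(length(free)) < cfg$noise_prob]
    if (length(hit)) {
      term <- ((hit - 1L) %/% cfg$n_atoms) + 1L
      mag <- abs(stats::rnorm(length(hit))) * cfg$strength_scale
      v[hit] <- .raw_unfavourable(term, mag)
    }
  }
  v
}

#' Generate a synthetic reference set
#'
#' Draws the true pattern, then generates `n_references` raw score tables in
#' the exporter's native sign convention: each reference independently shows
#' each true element as favourable with probability `presence_prob`
#' (half-normal magnitude, scale `strength_scale`), plus spurious repulsive
#' noise at rate `noise_prob` elsewhere. Fully reproducible from the config
#' seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `tables` (list of [atom_score_table()], raw signs),
#'   `cavity` (the shared [cavity_atoms()]), and `pattern` (the true-pattern
#'   matrix, as from [sample_true_pattern()]).
#' @export
generate_reference_set <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  cavity <- synthetic_cavity(cfg$n_atoms)
  pattern <- sample_true_pattern(cfg)
  tables <- with_local_seed(cfg$seed + 1L, {
    lapply(seq_len(cfg$n_references), function(i) {
      present <- stats::runif(nrow(pattern)) < cfg$presence_prob
      v <- .random_table(cfg, pattern[present, , drop = FALSE],
                         sprintf("ref_%02d", i))
      atom_score_table(cavity$atoms, v, sprintf("ref_%02d", i))
    })
  })
  list(tables = tables, cavity = cavity, pattern = pattern)
}

#' Generate a labelled active/decoy pose set
#'
#' Every pose makes the same number of favourable contacts as the true
#' pattern has elements. For an active, each pattern slot is realized at its
#' true element with probability `active_overlap` and at a uniformly random
#' site element otherwise; a decoy draws all its slots uniformly at random
#' (disjoint from the true pattern in expectation). At `active_overlap = 0`
#' actives are therefore distributionally identical to decoys, and at 1 they
#' reproduce the reference pattern exactly. Both classes get
#' spurious repulsive noise at rate `noise_prob`. Reproducible from the
#' config seed (a stream separate from the reference set's).
#'
#' @param cfg A [simulation_config()].
#' @param true_pattern Pattern matrix, as returned by
#'   [generate_reference_set()] / [sample_true_pattern()].
#' @return List with `tables` (named list of raw [atom_score_table()]s, ids
#'   like `active_001` / `decoy_001`) and `is_active` (named logical vector).
#' @export
generate_pose_set <- function(cfg, true_pattern) {
  stopifnot(inherits(cfg, "simulation_config"),
            is.matrix(true_pattern), ncol(true_pattern) == 2L,
            nrow(true_pattern) >= 1L,
            max(true_pattern[, 1L]) <= cfg$n_atoms,
            max(true_pattern[, 2L]) <= 8L)
  cavity <- synthetic_cavity(cfg$n_atoms)
  univ <- as.matrix(.favourable_universe(cfg$n_atoms))
  wid <- max(3L, nchar(max(cfg$n_actives, cfg$n_decoys, 1L)))
  ids <- c(if (cfg$n_actives > 0) sprintf("active_%0*d", wid, seq_len(cfg$n_actives)),
           if (cfg$n_decoys > 0) sprintf("decoy_%0*d", wid, seq_len(cfg$n_decoys)))
  is_active <- startsWith(ids, "active_")
  tables <- with_local_seed(cfg$seed + 2L, {
    lapply(seq_along(ids), function(i) {
      if (is_active[i]) {
        take_true <- stats::runif(nrow(true_pattern)) < cfg$active_overlap
        el <- rbind(true_pattern[take_true, , drop = FALSE],
                    univ[sample.int(nrow(univ), sum(!take_true)), , drop = FALSE])
      } else {
        el <- univ[sample.int(nrow(univ), nrow(true_pattern)), , drop = FALSE]
      }
      atom_score_table(cavity$atoms, .random_table(cfg, el, ids[i]), ids[i])
    })
  })
  names(tables) <- ids
  names(is_active) <- ids
  list(tables = tables, is_active = is_active)
}

#' Run one simulated screening campaign end to end
#'
#' Generates references and poses, merges the references, scores every pose,
#' and attaches a conventional score (the summed favourable energy of the
#' pose fingerprint, a stand-in for a docking fitness).
#'
#' @param cfg A [simulation_config()].
#' @return List with `ref` (the merged [`reference_padif`][merge_references]),
#'   `scores` (the [score_poses()] data.frame), `conventional` (named numeric
#'   vector), `is_active` (named logical), `pattern`.
#' @export
simulate_screen <- function(cfg) {
  refs <- generate_reference_set(cfg)
  ref <- merge_references(lapply(refs$tables, make_padif))
  poses <- generate_pose_set(cfg, refs$pattern)
  fps <- lapply(poses$tables, make_padif)
  scores <- score_poses(ref, fps)
  conventional <- vapply(fps, function(p) -sum(p$values), numeric(1))
  list(ref = ref, scores = scores, conventional = conventional,
       is_active = poses$is_active, pattern = refs$pattern)
}
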