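#' Idealized single-domain test structure
#'
#' Builds a deterministic Calpha trace with one of three simple folds —
#' an alpha helix (rise 1.5 A, ~100 degrees per residue, radius 2.3 A), a
#' beta hairpin (two antiparallel extended strands, 3.8 A Calpha spacing),
#' or a mixed helix+strand — optionally decorated with cysteines whose SG
#' atoms sit 2.8 A off the Calpha and, when `plant_fe` is set, an iron
#' placed 2.25 A from each SG (inside the Fe-S bonding window). The
#' geometry is only meant to drive the elastic network and the coordination
#' filter, not to be physically realistic.
#'
#' @param n_residues domain length (>= 6).
#' @param fold one of `"helix"`, `"hairpin"`, `"mixed"`.
#' @param cys_positions residue positions (1-based) to make cysteine.
#' @param plant_fe place an iron site next to each cysteine SG?
#' @param seed integer seed controlling the sequence draw.
#' @param chain chain identifier.
#' @param source_id structure identifier.
#' @return A [ca_structure()]; when `plant_fe` is `TRUE` the iron sites are
#'   attached as the `fe_sites` attribute (same columns as
#'   [extract_fe_sites()]).
#' @export
make_toy_domain <- function(n_residues = 30L, fold = c("helix", "hairpin", "mixed"),
                            cys_positions = integer(0), plant_fe = FALSE,
                            seed = 1L, chain = "A", source_id = "toy") {
  fold <- match.arg(fold)
  n <- as.integer(n_residues)
  stopifnot(n >= 6)
  xyz <- switch(fold,
    helix = helix_trace(n),
    hairpin = hairpin_trace(n),
    mixed = {
      n1 <- ceiling(n / 2)
      a <- helix_trace(n1)
      b <- strand_trace(n - n1)
      b <- sweep(b, 2, a[n1, ] + c(3.0, 0, 2.2), "+")
      rbind(a, b)
    })
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  alphabet <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]   # no C
  aa <- sample(alphabet, n, replace = TRUE)
  cys_positions <- as.integer(cys_positions)
  stopifnot(all(cys_positions >= 1 & cys_positions <= n))
  aa[cys_positions] <- "C"
  df <- data.frame(chain = chain, seq_index = seq_len(n),
                   auth_resnum = seq_len(n), insert = "", aa = aa,
                   ca_x = xyz[, 1], ca_y = xyz[, 2], ca_z = xyz[, 3],
                   sg_x = NA_real_, sg_y = NA_real_, sg_z = NA_real_,
                   stringsAsFactors = FALSE)
  struct <- place_sg(ca_structure(df, source_id = source_id))
  if (plant_fe) attr(struct, "fe_sites") <- fe_from_sg(struct)
  struct
}

helix_trace <- function(n) {
  t <- seq_len(n) - 1
  ang <- t * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * t)
}

strand_trace <- function(n) {
  t <- seq_len(n) - 1
  cbind(0.3 * (t %% 2), 0, 3.6 * t)
}

hairpin_trace <- function(n) {
  n1 <- ceiling(n / 2)
  up <- strand_trace(n1)
  down <- strand_trace(n - n1)
  down <- cbind(4.8 + down[, 1], down[, 2],
                up[n1, 3] + 1.2 - down[, 3])
  rbind(up, down)
}

# SG placed 2.8 A from the Calpha, directed away from the structure centroid
# so irons planted beyond it stay on the outside.
place_sg <- function(struct) {
  cys <- which(struct$aa == "C")
  if (length(cys) == 0) return(struct)
  xyz <- ca_coords(struct)
  centroid <- colMeans(xyz)
  for (i in cys) {
    dir <- xyz[i, ] - centroid
    nrm <- sqrt(sum(dir^2))
    dir <- if (nrm < 1e-6) c(1, 0, 0) else dir / nrm
    sg <- xyz[i, ] + 2.8 * dir
    struct$sg_x[i] <- sg[1]; struct$sg_y[i] <- sg[2]; struct$sg_z[i] <- sg[3]
  }
  struct
}

# One iron per cysteine SG, 2.25 A further out along the Calpha->SG axis.
fe_from_sg <- function(struct) {
  cys <- which(!is.na(struct$sg_x))
  if (length(cys) == 0)
    return(data.frame(fe_x = numeric(0), fe_y = numeric(0), fe_z = numeric(0),
                      cluster_name = character(0), cluster_id = character(0),
                      stringsAsFactors = FALSE))
  sg <- as.matrix(struct[cys, c("sg_x", "sg_y", "sg_z")])
  ca <- ca_coords(struct)[cys, , drop = FALSE]
  dir <- sg - ca
  dir <- dir / sqrt(rowSums(dir^2))
  fe <- sg + 2.25 * dir
  data.frame(fe_x = fe[, 1], fe_y = fe[, 2], fe_z = fe[, 3],
             cluster_name = "FE",
             cluster_id = sprintf("FE_%s_%d", struct$chain[cys],
                                  struct$seq_index[cys]),
             stringsAsFactors = FALSE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Embedded-domain fixture with known ground truth
#'
#' Concatenates `n_copies` of a toy domain, separated by cysteine-free
#' random-coil linkers, into one chain — emulating a small domain embedded
#' (repeatedly) inside a larger protein. Iron sites are planted next to
#' each copy's cysteines after any coordinate noise is applied, so the
#' Fe-S coordination geometry stays inside the bonding window by
#' construction while the backbone trace carries the noise.
#'
#' @param domain_length residues per copy.
#' @param n_copies number of embedded copies (>= 1).
#' @param linker_length residues per linker.
#' @param fold passed to [make_toy_domain()].
#' @param cys_positions cysteine positions within each copy (defaults to
#'   four interior positions, mirroring a half-ferredoxin ligand spacing).
#' @param noise_rmsd Gaussian coordinate noise, Angstrom RMSD.
#' @param seed integer seed (sequence, linker geometry, noise).
#' @param source_id structure identifier.
#' @return List with `structure` (a [ca_structure()]), `fe_sites`, and
#'   `ground_truth` (data frame `copy`, `start`, `end` in seq_index).
#' @export
make_embedded_fixture <- function(domain_length = 30L, n_copies = 2L,
                                  linker_length = 30L,
                                  fold = "helix",
                                  cys_positions = NULL,
                                  noise_rmsd = 0, seed = 1L,
                                  source_id = "embedded_fixture") {
  stopifnot(n_copies >= 1, linker_length >= 0, noise_rmsd >= 0)
  if (is.null(cys_positions)) {
    lo <- max(2L, round(domain_length * 0.3))
    hi <- min(domain_length - 1L, round(domain_length * 0.75))
    cys_positions <- unique(round(seq(lo, hi, length.out = 4)))
  }
  domain <- make_toy_domain(domain_length, fold = fold,
                            cys_positions = cys_positions, plant_fe = FALSE,
                            seed = seed, source_id = "domain")
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed + 1000L)
  linker_alphabet <- strsplit("AGSTVDE", "")[[1]]

  rows <- list()
  gt <- list()
  cursor <- c(0, 0, 0)       # attachment point for the next segment
  pos <- 0L
  for (k in seq_len(n_copies)) {
    d <- domain
    shift <- cursor - ca_coords(d)[1, ] + c(0, 0, 3.8)
    d$ca_x <- d$ca_x + shift[1]; d$ca_y <- d$ca_y + shift[2]
    d$ca_z <- d$ca_z + shift[3]
    has_sg <- !is.na(d$sg_x)
    d$sg_x[has_sg] <- d$sg_x[has_sg] + shift[1]
    d$sg_y[has_sg] <- d$sg_y[has_sg] + shift[2]
    d$sg_z[has_sg] <- d$sg_z[has_sg] + shift[3]
    gt[[k]] <- data.frame(copy = k, start = pos + 1L,
                          end = pos + nrow(d))
    rows[[length(rows) + 1L]] <- as.data.frame(d)
    pos <- pos + nrow(d)
    cursor <- as.numeric(ca_coords(d)[nrow(d), ])
    if (k < n_copies && linker_length > 0) {
      lx <- linker_trace(cursor, linker_length)
      ld <- data.frame(chain = "A", seq_index = 1L,
                       auth_resnum = 1L, insert = "",
                       aa = sample(linker_alphabet, linker_length,
                                   replace = TRUE),
                       ca_x = lx[, 1], ca_y = lx[, 2], ca_z = lx[, 3],
                       sg_x = NA_real_, sg_y = NA_real_, sg_z = NA_real_,
                       stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- ld
      pos <- pos + linker_length
      cursor <- as.numeric(lx[linker_length, ])
    }
  }
  df <- do.call(rbind, rows)
  df$auth_resnum <- seq_len(nrow(df))
  struct <- ca_structure(df, source_id = source_id)
  if (noise_rmsd > 0)
    struct <- perturb_structure(struct, noise_rmsd, seed = seed + 2000L)
  fe <- fe_from_sg(struct)
  attr(struct, "fe_sites") <- fe
  list(structure = struct, fe_sites = fe,
       ground_truth = do.call(rbind, gt))
}

# Compact irregular helical segment continuing from `from` along +z. A
# thin extended thread would act as a floppy mechanism with spurious
# near-zero modes; a coiled linker keeps the network stiff while still
# separating the flanking copies beyond the spring cutoff.
linker_trace <- function(from, n) {
  hx <- helix_trace(n) + matrix(stats::rnorm(3 * n, 0, 0.3), n, 3)
  sweep(hx, 2, from + c(2.2, 0, 3.1) - hx[1, ], "+")
}

#' Gaussian coordinate perturbation
#'
#' Displaces every residue by an i.i.d. Gaussian vector scaled so the
#' expected coordinate RMSD equals `rmsd`; the cysteine SG follows its
#' residue's Calpha rigidly.
#'
#' @param structure a [ca_structure()].
#' @param rmsd requested RMSD in Angstrom (0 returns the input unchanged).
#' @param seed integer seed.
#' @return The perturbed [ca_structure()].
#' @export
perturb_structure <- function(structure, rmsd, seed = 1L) {
  stopifnot(rmsd >= 0)
  if (rmsd == 0) return(structure)
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(seed)
  n <- nrow(structure)
  disp <- matrix(stats::rnorm(3 * n, sd = rmsd / sqrt(3)), n, 3)
  structure$ca_x <- structure$ca_x + disp[, 1]
  structure$ca_y <- structure$ca_y + disp[, 2]
  structure$ca_z <- structure$ca_z + disp[, 3]
  has_sg <- !is.na(structure$sg_x)
  structure$sg_x[has_sg] <- structure$sg_x[has_sg] + disp[has_sg, 1]
  structure$sg_y[has_sg] <- structure$sg_y[has_sg] + disp[has_sg, 2]
  structure$sg_z[has_sg] <- structure$sg_z[has_sg] + disp[has_sg, 3]
  structure
}
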