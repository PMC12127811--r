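## Synthetic multi-modal glioma phantom cohorts.
##
## Phantoms reproduce, in parametric form, the imaging signatures the
## genotyping network is designed to exploit:
##   * IDH-mutant lesions: uniformly hyperintense on T2 while FLAIR shows a
##     hyperintense rim around a hypointense core (the T2-FLAIR mismatch sign);
##   * IDH-wild-type lesions: annular contrast enhancement on T1-ce with
##     central necrosis;
##   * ATRX-mutant lesions: peritumoral edema that is both rarer and thinner;
##   * 1p/19q-codeleted lesions: blurred lesion margins.
## Genotype triples obey the unidirectional dependency rules (wild-type IDH or
## mutant ATRX each imply non-codeleted 1p/19q) with configurable adherence.

MODALITIES <- c("t1", "t1ce", "t2", "flair")

#' Cohort specification
#'
#' Parameters of a synthetic phantom cohort: size, geometry, genotype
#' marginals and dependency-rule adherence, missing-modality pattern weights
#' and noise level.
#'
#' @slot n_subjects number of subjects
#' @slot volume_shape voxel dimensions of each modality volume
#' @slot class_fractions named minority fractions for `idh` (mutant),
#'   `atrx` (mutant) and `codel` (1p/19q codeleted)
#' @slot rule_adherence probability that the genotype dependency rules are
#'   enforced for a subject
#' @slot missing_weights probabilities of the modality patterns
#'   `full`, `no_t1ce` (T1+T2+FLAIR) and `no_t1` (T1-ce+T2+FLAIR)
#' @slot lesion_radius_range min/max lesion semi-axis in voxels
#' @slot noise_sd standard deviation of additive Gaussian intensity noise
#' @slot edema_prob probability that an ATRX-wild-type lesion carries an
#'   edema halo (halved, together with halo thickness, for ATRX mutants)
#' @slot seed RNG seed used by [simulateCohort()]
#' @export
setClass("CohortSpec", representation(
  n_subjects = "integer",
  volume_shape = "integer",
  class_fractions = "numeric",
  rule_adherence = "numeric",
  missing_weights = "numeric",
  lesion_radius_range = "numeric",
  noise_sd = "numeric",
  edema_prob = "numeric",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msgs <- character()
  f <- object@class_fractions
  if (!all(c("idh", "atrx", "codel") %in% names(f)))
    msgs <- c(msgs, "class_fractions needs entries idh, atrx, codel")
  if (any(f < 0 | f > 1)) msgs <- c(msgs, "class fractions must lie in [0,1]")
  if (object@rule_adherence < 0 || object@rule_adherence > 1)
    msgs <- c(msgs, "rule_adherence must lie in [0,1]")
  w <- object@missing_weights
  if (length(w) != 3L || any(w < 0) || abs(sum(w) - 1) > 1e-8)
    msgs <- c(msgs, "missing_weights must be 3 nonnegative values summing to 1")
  r <- object@lesion_radius_range
  if (any(r <= 0) || max(r) >= min(object@volume_shape) / 2)
    msgs <- c(msgs, "lesion radii must be positive and smaller than half the smallest volume dimension")
  if (object@rule_adherence > 0 && all(c("idh", "atrx", "codel") %in% names(f))) {
    attainable <- f[["idh"]] * (1 - f[["atrx"]])
    if (f[["codel"]] > attainable + 1e-12)
      msgs <- c(msgs, sprintf(
        "codel fraction %.3f unattainable under the dependency rules (max %.3f = idh * (1 - atrx))",
        f[["codel"]], attainable))
  }
  if (length(msgs)) msgs else TRUE
})

#' Create a cohort specification
#'
#' @param n_subjects number of subjects to generate
#' @param volume_shape integer voxel dimensions (default the BraTS-style
#'   240 x 240 x 155 grid)
#' @param class_fractions minority-class fractions; defaults match a cohort in
#'   which IDH-wild-type cases are about twice as frequent as mutants and ATRX
#'   mutants and 1p/19q codeletions make up 20% and 11%
#' @param rule_adherence probability of enforcing the genotype dependency
#'   rules per subject (1 = always)
#' @param missing_weights probabilities of the patterns full / missing T1-ce /
#'   missing T1; T2 and FLAIR are never dropped
#' @param lesion_radius_range lesion semi-axis range in voxels; default scales
#'   with the volume
#' @param noise_sd additive Gaussian noise inside the brain mask
#' @param edema_prob edema probability for ATRX-wild-type lesions
#' @param seed integer seed consumed by [simulateCohort()]
#' @return a [CohortSpec-class] object
#' @export
cohortSpec <- function(n_subjects,
                       volume_shape = c(240L, 240L, 155L),
                       class_fractions = c(idh = 0.33, atrx = 0.20, codel = 0.11),
                       rule_adherence = 1.0,
                       missing_weights = c(full = 1, no_t1ce = 0, no_t1 = 0),
                       lesion_radius_range = NULL,
                       noise_sd = 0.05,
                       edema_prob = 0.9,
                       seed = 1L) {
  if (is.null(lesion_radius_range))
    lesion_radius_range <- round(c(0.10, 0.18) * min(volume_shape))
  methods::new("CohortSpec",
    n_subjects = as.integer(n_subjects),
    volume_shape = as.integer(volume_shape),
    class_fractions = class_fractions,
    rule_adherence = rule_adherence,
    missing_weights = missing_weights / sum(missing_weights),
    lesion_radius_range = as.numeric(lesion_radius_range),
    noise_sd = noise_sd,
    edema_prob = edema_prob,
    seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@n_subjects, "subjects,",
      paste(object@volume_shape, collapse = "x"), "voxels\n")
  cat("  minority fractions:",
      paste(sprintf("%s=%.2f", names(object@class_fractions),
                    object@class_fractions), collapse = ", "), "\n")
  cat("  rule adherence:", object@rule_adherence,
      " noise sd:", object@noise_sd, "\n")
})

#' One subject: volumes, availability mask and genotype labels
#'
#' @slot subject_id subject identifier
#' @slot volumes named list of 3D intensity arrays (subset of t1, t1ce, t2,
#'   flair), all sharing one shape
#' @slot availability logical flags ordered (T1, T1-ce, T2, FLAIR)
#' @slot labels named integer genotype triple (idh, atrx, codel), each 0/1
#' @slot meta free-form provenance (for rendered phantoms: lesion center,
#'   semi-axes, edema flag and halo thickness)
#' @export
setClass("SubjectSample", representation(
  subject_id = "character",
  volumes = "list",
  availability = "logical",
  labels = "integer",
  meta = "list"
))

setValidity("SubjectSample", function(object) {
  msgs <- character()
  if (length(object@availability) != 4L)
    msgs <- c(msgs, "availability must have 4 flags")
  if (!identical(sort(names(object@volumes)),
                 sort(MODALITIES[object@availability])))
    msgs <- c(msgs, "availability flags must mark exactly the present volumes")
  shp <- lapply(object@volumes, dim)
  if (length(shp) > 1 && !all(vapply(shp, identical, logical(1), shp[[1]])))
    msgs <- c(msgs, "all present volumes must share one shape")
  lb <- object@labels
  if (!all(c("idh", "atrx", "codel") %in% names(lb)) || !all(lb %in% 0:1))
    msgs <- c(msgs, "labels must be a 0/1 triple (idh, atrx, codel)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SubjectSample", function(object) {
  cat("SubjectSample", object@subject_id, "|",
      paste(names(object@volumes), collapse = "+"), "|",
      paste(sprintf("%s=%d", names(object@labels), object@labels),
            collapse = " "), "\n")
})

#' Genotype labels of a sample or cohort
#' @param x a `SubjectSample` or a list of them
#' @return named integer vector, or a data.frame for a list
#' @export
genotypeLabels <- function(x) {
  if (methods::is(x, "SubjectSample")) return(x@labels)
  df <- do.call(rbind, lapply(x, function(s) as.data.frame(as.list(s@labels))))
  df$subject_id <- vapply(x, function(s) s@subject_id, character(1))
  df[c("subject_id", "idh", "atrx", "codel")]
}

#' Sample genotype triples under the dependency rules
#'
#' IDH and ATRX statuses are independent Bernoulli draws at their target
#' minority fractions. With probability `rule_adherence` per subject, the
#' 1p/19q status is drawn conditionally so that wild-type IDH or mutant ATRX
#' force non-codeletion; the conditional rate is chosen so the codeletion
#' marginal still matches its target. Otherwise 1p/19q is an independent draw.
#'
#' Consumes the current RNG stream; seed with [set.seed()] (or use
#' [simulateCohort()]).
#'
#' @param spec a [CohortSpec-class]
#' @return integer matrix with columns idh, atrx, codel
#' @export
sampleGenotypes <- function(spec) {
  methods::validObject(spec)
  n <- spec@n_subjects
  f <- spec@class_fractions
  idh <- as.integer(stats::runif(n) < f[["idh"]])
  atrx <- as.integer(stats::runif(n) < f[["atrx"]])
  enforce <- stats::runif(n) < spec@rule_adherence
  p_cond <- if (f[["idh"]] * (1 - f[["atrx"]]) > 0)
    min(1, f[["codel"]] / (f[["idh"]] * (1 - f[["atrx"]]))) else 0
  u <- stats::runif(n)
  codel_rule <- as.integer(idh == 1L & atrx == 0L & u < p_cond)
  codel_free <- as.integer(u < f[["codel"]])
  codel <- ifelse(enforce, codel_rule, codel_free)
  cbind(idh = idh, atrx = atrx, codel = as.integer(codel))
}

## smoothstep ramp: ~1 well inside radius r0, ~0 outside, transition width w
.edge <- function(rho, r0, w) {
  t <- (r0 + w / 2 - rho) / w
  t[t < 0] <- 0
  t[t > 1] <- 1
  t * t * (3 - 2 * t)
}

## squared normalized ellipsoid coordinate on the voxel grid
.ellipsoidRho2 <- function(shape, center, semi) {
  ax <- ((seq_len(shape[1]) - center[1]) / semi[1])^2
  ay <- ((seq_len(shape[2]) - center[2]) / semi[2])^2
  az <- ((seq_len(shape[3]) - center[3]) / semi[3])^2
  outer(outer(ax, ay, "+"), az, "+")
}

#' Render one subject's phantom volumes from its genotype
#'
#' Places an axis-aligned ellipsoidal lesion (random center and semi-axes)
#' inside a smooth ellipsoidal "brain" of baseline intensity 1 (zero outside,
#' skull-stripped convention) and applies the genotype-conditional intensity
#' signatures. Consumes the RNG stream.
#'
#' @param labels named or ordered 0/1 triple (idh, atrx, codel)
#' @param spec a [CohortSpec-class]
#' @param subject_id identifier for the sample
#' @return a [SubjectSample-class] with all four modalities
#' @export
renderSubject <- function(labels, spec, subject_id = "sub-001") {
  labels <- as.integer(labels)
  names(labels) <- c("idh", "atrx", "codel")
  shape <- spec@volume_shape
  rr <- spec@lesion_radius_range
  if (max(rr) >= min(shape) / 2)
    stop("lesion radius range incompatible with volume shape ",
         paste(shape, collapse = "x"))

  brain_semi <- 0.45 * shape
  brain <- .edge(sqrt(.ellipsoidRho2(shape, shape / 2, brain_semi)), 1, 0.1)
  mask <- brain > 0

  semi <- stats::runif(3, rr[1], rr[2])
  center <- shape / 2 + stats::runif(3, -0.12, 0.12) * shape
  rho <- sqrt(.ellipsoidRho2(shape, center, semi))

  ## blurred margins for 1p/19q codeletion
  w <- if (labels[["codel"]] == 1L) 0.55 else 0.15
  m_lesion <- .edge(rho, 1, w)
  m_core <- .edge(rho, 0.6, w)
  m_rim <- pmax(m_lesion - m_core, 0)

  ## edema: rarer and thinner for ATRX mutants
  p_ed <- spec@edema_prob * if (labels[["atrx"]] == 1L) 0.5 else 1
  halo_h <- if (labels[["atrx"]] == 1L) 0.25 else 0.5
  has_edema <- stats::runif(1) < p_ed
  m_halo <- if (has_edema) pmax(.edge(rho, 1 + halo_h, w) - m_lesion, 0) else 0

  t1 <- brain - 0.2 * m_lesion
  t2 <- brain + 1.0 * m_lesion + 0.5 * m_halo
  if (labels[["idh"]] == 1L) {
    t1ce <- brain + 0.1 * m_lesion
    flair <- brain + 1.0 * m_rim - 0.5 * m_core + 0.5 * m_halo
  } else {
    t1ce <- brain + 1.0 * m_rim - 0.7 * m_core
    flair <- brain + 0.8 * m_lesion + 0.5 * m_halo
  }

  vols <- list(t1 = t1, t1ce = t1ce, t2 = t2, flair = flair)
  vols <- lapply(vols, function(v) {
    if (spec@noise_sd > 0) {
      nz <- stats::rnorm(sum(mask), 0, spec@noise_sd)
      v[mask] <- v[mask] + nz
    }
    v[!mask] <- 0
    v
  })

  methods::new("SubjectSample", subject_id = subject_id, volumes = vols,
               availability = rep(TRUE, 4L), labels = labels,
               meta = list(center = center, semi = semi, edge_width = w,
                           has_edema = has_edema, halo = halo_h))
}

#' Drop modalities according to the missing-pattern weights
#'
#' Patterns are: all four modalities; T1+T2+FLAIR (T1-ce missing);
#' T1-ce+T2+FLAIR (T1 missing). T2 and FLAIR are never dropped. Consumes the
#' RNG stream.
#'
#' @param sample a full-modality [SubjectSample-class]
#' @param spec a [CohortSpec-class] carrying the pattern weights
#' @return the sample with its volumes and availability mask updated
#' @export
applyMissingModalities <- function(sample, spec) {
  stopifnot(length(sample@volumes) == 4L)
  pattern <- sample.int(3L, 1L, prob = spec@missing_weights)
  drop <- switch(pattern, NULL, "t1ce", "t1")
  if (!is.null(drop)) {
    sample@volumes[[drop]] <- NULL
    sample@availability[match(drop, MODALITIES)] <- FALSE
  }
  methods::validObject(sample)
  sample
}

#' Generate a full cohort
#'
#' Seeds the RNG from `spec@seed`, draws genotypes, renders each subject and
#' applies the missing-modality patterns. Fully deterministic for a fixed
#' spec.
#'
#' @param spec a [CohortSpec-class]
#' @return list of [SubjectSample-class] objects
#' @export
simulateCohort <- function(spec) {
  set.seed(spec@seed)
  gt <- sampleGenotypes(spec)
  lapply(seq_len(spec@n_subjects), function(i) {
    s <- renderSubject(gt[i, ], spec, subject_id = sprintf("sub-%03d", i))
    applyMissingModalities(s, spec)
  })
}

#' Write a cohort to NIfTI volumes plus a label table
#'
#' One gzipped NIfTI file per present modality per subject
#' (`<id>_<modality>.nii.gz`) and a `labels.csv` with the genotype triple and
#' availability flags. Intensities round-trip exactly (float64 storage).
#'
#' @param samples list of [SubjectSample-class]
#' @param out_dir output directory, created if needed
#' @return invisibly, a data.frame manifest of written files
#' @export
writeCohort <- function(samples, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rows <- list()
  files <- list()
  for (s in samples) {
    for (m in names(s@volumes)) {
      path <- file.path(out_dir, paste0(s@subject_id, "_", m, ".nii.gz"))
      RNifti::writeNifti(s@volumes[[m]], path, datatype = "double")
      files[[length(files) + 1L]] <-
        data.frame(subject_id = s@subject_id, modality = m, file = path)
    }
    av <- as.integer(s@availability)
    rows[[length(rows) + 1L]] <- data.frame(
      subject_id = s@subject_id,
      idh = s@labels[["idh"]], atrx = s@labels[["atrx"]],
      codel = s@labels[["codel"]],
      has_t1 = av[1], has_t1ce = av[2], has_t2 = av[3], has_flair = av[4])
  }
  labels <- do.call(rbind, rows)
  utils::write.csv(labels, file.path(out_dir, "labels.csv"), row.names = FALSE)
  invisible(do.call(rbind, files))
}

#' Read a cohort written by [writeCohort()] (or any directory following the
#' same suffix convention plus label table)
#'
#' @param dir cohort directory containing `labels.csv`
#' @return list of [SubjectSample-class]
#' @export
readCohort <- function(dir) {
  lab_path <- file.path(dir, "labels.csv")
  if (!file.exists(lab_path)) stop("no labels.csv found in ", dir)
  labels <- utils::read.csv(lab_path)
  lapply(seq_len(nrow(labels)), function(i) {
    row <- labels[i, ]
    av <- as.logical(c(row$has_t1, row$has_t1ce, row$has_t2, row$has_flair))
    vols <- list()
    for (m in MODALITIES[av]) {
      path <- file.path(dir, paste0(row$subject_id, "_", m, ".nii.gz"))
      if (!file.exists(path)) stop("missing volume: ", path)
      v <- RNifti::readNifti(path)
      vols[[m]] <- array(as.numeric(v), dim = dim(v))
    }
    methods::new("SubjectSample", subject_id = as.character(row$subject_id),
                 volumes = vols, availability = av,
                 labels = c(idh = as.integer(row$idh),
                            atrx = as.integer(row$atrx),
                            codel = as.integer(row$codel)))
  })
}
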