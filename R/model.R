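#' Construct a cyclin network model specification
#'
#' Builds one of four nested variants of a transcriptional regulation model
#' for the budding-yeast cyclins CLN3, CLN2, CLB5 and CLB2 and the
#' transcription-factor subunits that drive their periodic expression
#' (SWI4 for SBF, NDD1 for Mcm1-Fkh, SWI5 for Swi/Snf, plus HCM1 and the
#' transcriptional repressor YOX1 in the larger variants).
#'
#' Each gene is represented by two species, its mRNA and its protein, in
#' micromolar units with time in seconds. Every gene has exactly one
#' activating transcription factor, at most one transcriptional inhibitor,
#' and at most one inhibitor of protein degradation.
#'
#' The four variants are nested:
#' \describe{
#'   \item{1}{7 genes; SWI5 -> CLN3 -> SWI4 -> \{CLN2, CLB5, NDD1\};
#'            NDD1 -> \{CLB2, SWI5\}.}
#'   \item{2}{adds HCM1 between SWI4 and NDD1 (SWI4 -> HCM1 -> NDD1),
#'            introducing a delay in the activation cascade.}
#'   \item{3}{adds the repressor YOX1 (activated by SWI4) which inhibits
#'            transcription of both SWI4 and CLN3: a negative feedback loop.}
#'   \item{4}{adds inhibition of NDD1 protein degradation by CLN2 protein,
#'            emulating CLN2-mediated inactivation of the anaphase
#'            promoting complex.}
#' }
#'
#' @param variant Integer in 1..4 selecting the network variant.
#' @param period Cell-cycle period in seconds (default 4800 = 80 min).
#' @return An object of class \code{cyclin_model}: a list with elements
#'   \code{variant}, \code{genes} (data frame with columns \code{name},
#'   \code{activator}, \code{transcription_inhibitor},
#'   \code{degradation_inhibitor}), \code{species} (mRNA then protein
#'   names) and \code{period}.
#' @examples
#' m <- build_model(1)
#' nrow(m$genes)      # 7
#' length(m$species)  # 14
#' @export
build_model <- function(variant, period = 4800) {
  if (length(variant) != 1L || !is.numeric(variant) || is.na(variant) ||
      variant != as.integer(variant) || !(variant %in% 1:4)) {
    stop("`variant` must be one of 1, 2, 3, 4 (nested model variants)",
         call. = FALSE)
  }
  variant <- as.integer(variant)
  g <- function(name, act, tinh = NA_character_, dinh = NA_character_) {
    data.frame(name = name, activator = act,
               transcription_inhibitor = tinh,
               degradation_inhibitor = dinh,
               stringsAsFactors = FALSE)
  }
  genes <- rbind(
    g("CLN3", "SWI5", tinh = if (variant >= 3) "YOX1" else NA_character_),
    g("CLN2", "SWI4"),
    g("CLB5", "SWI4"),
    g("CLB2", "NDD1"),
    g("SWI4", "CLN3", tinh = if (variant >= 3) "YOX1" else NA_character_),
    g("NDD1", if (variant >= 2) "HCM1" else "SWI4",
      dinh = if (variant == 4) "CLN2" else NA_character_),
    g("SWI5", "NDD1")
  )
  if (variant >= 2) genes <- rbind(genes, g("HCM1", "SWI4"))
  if (variant >= 3) genes <- rbind(genes, g("YOX1", "SWI4"))
  model_spec(genes, variant = variant, period = period)
}

#' Construct a model specification from a gene table
#'
#' Lower-level constructor behind [build_model()], also used for reduced
#' test systems such as the single self-activating gene of
#' [single_gene_model()].
#'
#' @param genes Data frame with columns \code{name}, \code{activator},
#'   \code{transcription_inhibitor}, \code{degradation_inhibitor}
#'   (the last two may be \code{NA}).
#' @param variant Optional integer tag recording which preset variant this
#'   is; \code{NA} for custom models.
#' @param period Cell-cycle period in seconds.
#' @return A \code{cyclin_model} object.
#' @export
model_spec <- function(genes, variant = NA_integer_, period = 4800) {
  stopifnot(is.data.frame(genes),
            all(c("name", "activator", "transcription_inhibitor",
                  "degradation_inhibitor") %in% names(genes)))
  if (!is.numeric(period) || length(period) != 1L || period <= 0)
    stop("`period` must be a positive duration in seconds", call. = FALSE)
  if (anyDuplicated(genes$name))
    stop("duplicated gene names in model specification", call. = FALSE)
  if (any(is.na(genes$activator)))
    stop("every gene must have an activating transcription factor",
         call. = FALSE)
  refs <- c(genes$activator,
            genes$transcription_inhibitor[!is.na(genes$transcription_inhibitor)],
            genes$degradation_inhibitor[!is.na(genes$degradation_inhibitor)])
  missing <- setdiff(refs, genes$name)
  if (length(missing) > 0)
    stop("regulator(s) not present in the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(
    list(variant = as.integer(variant),
         genes = genes,
         species = c(paste0("mRNA_", genes$name),
                     paste0("protein_", genes$name)),
         period = as.numeric(period)),
    class = "cyclin_model")
}

#' Reduced single-gene model for calibration studies
#'
#' A one-gene system whose protein activates its own transcription. With
#' induced transcription weaker than turnover (alpha * kappa <
#' deltam * deltap) the system is a stable linear ODE, which makes it a
#' convenient reduced problem for sampler calibration and parameter
#' recovery studies: the relative time-course channel carries kinetic
#' information through the synchronization-release transient while the
#' absolute channel sets the concentration scale.
#'
#' @param name Gene name used for the single gene.
#' @param period Cell-cycle period in seconds.
#' @return A \code{cyclin_model} with one gene and two species.
#' @export
single_gene_model <- function(name = "G1", period = 4800) {
  genes <- data.frame(name = name, activator = name,
                      transcription_inhibitor = NA_character_,
                      degradation_inhibitor = NA_character_,
                      stringsAsFactors = FALSE)
  model_spec(genes, variant = NA_integer_, period = period)
}

#' @export
print.cyclin_model <- function(x, ...) {
  cat(sprintf("cyclin network model (variant %s): %d genes, %d species, period %.0f s\n",
              ifelse(is.na(x$variant), "custom", x$variant),
              nrow(x$genes), length(x$species), x$period))
  invisible(x)
}

#' Parameter inventory of a model
#'
#' Lists every kinetic parameter, initial condition and error scale of a
#' model, with its storage scale and unit. All parameters are stored on a
#' log10 scale except the Hill exponents \code{h_*}, which are linear.
#'
#' Per gene g: basal transcription rate \code{beta_g} (uM/s), induced
#' transcription rate \code{alpha_g} (1/s), protein degradation rate
#' \code{deltap_g} (1/s), initial conditions \code{m0_g} and \code{p0_g}
#' (uM). Shared: mRNA degradation rate \code{deltam} (1/s) and translation
#' rate \code{kappa} (1/s). Per transcription-inhibition edge on gene g:
#' half-inhibition constant \code{K_tx_g} (uM) and Hill exponent
#' \code{h_tx_g}; likewise \code{K_deg_g}, \code{h_deg_g} for
#' degradation-inhibition edges. Error scales \code{sigma_tc} (natural-log
#' ratio units) and \code{sigma_ss} (log10 concentration units).
#'
#' @param model A \code{cyclin_model}.
#' @return Data frame with columns \code{name}, \code{kind}, \code{gene},
#'   \code{scale} ("log10" or "linear") and \code{unit}.
#' @export
param_info <- function(model) {
  stopifnot(inherits(model, "cyclin_model"))
  gn <- model$genes$name
  row <- function(name, kind, gene, scale, unit)
    data.frame(name = name, kind = kind, gene = gene, scale = scale,
               unit = unit, stringsAsFactors = FALSE)
  out <- list()
  for (g in gn) {
    out[[length(out) + 1L]] <- row(paste0("beta_", g), "beta", g, "log10", "uM/s")
    out[[length(out) + 1L]] <- row(paste0("alpha_", g), "alpha", g, "log10", "1/s")
    out[[length(out) + 1L]] <- row(paste0("deltap_", g), "deltap", g, "log10", "1/s")
  }
  out[[length(out) + 1L]] <- row("deltam", "deltam", NA_character_, "log10", "1/s")
  out[[length(out) + 1L]] <- row("kappa", "kappa", NA_character_, "log10", "1/s")
  for (g in gn[!is.na(model$genes$transcription_inhibitor)]) {
    out[[length(out) + 1L]] <- row(paste0("K_tx_", g), "K_tx", g, "log10", "uM")
    out[[length(out) + 1L]] <- row(paste0("h_tx_", g), "h_tx", g, "linear", "")
  }
  for (g in gn[!is.na(model$genes$degradation_inhibitor)]) {
    out[[length(out) + 1L]] <- row(paste0("K_deg_", g), "K_deg", g, "log10", "uM")
    out[[length(out) + 1L]] <- row(paste0("h_deg_", g), "h_deg", g, "linear", "")
  }
  for (g in gn) {
    out[[length(out) + 1L]] <- row(paste0("m0_", g), "m0", g, "log10", "uM")
    out[[length(out) + 1L]] <- row(paste0("p0_", g), "p0", g, "log10", "uM")
  }
  out[[length(out) + 1L]] <- row("sigma_tc", "sigma_tc", NA_character_, "log10", "")
  out[[length(out) + 1L]] <- row("sigma_ss", "sigma_ss", NA_character_, "log10", "")
  do.call(rbind, out)
}

#' Default prior bounds for a model
#'
#' Independent uniform priors on the storage scale of each parameter
#' (log10 for all but the Hill exponents). Defaults: rate parameters span
#' 1e-6 to 10 (in 1/s or uM/s as dimensioned), concentrations (half
#' inhibition constants and initial conditions) 1e-5 to 10 uM, error
#' scales 1e-2 to 10, Hill exponents uniform on [1, 4] linearly. All
#' bounds are configuration: override via the \code{overrides} argument
#' (named list of \code{c(lower, upper)} on the storage scale).
#'
#' @param model A \code{cyclin_model}.
#' @param overrides Named list of length-2 numeric vectors replacing the
#'   default \code{c(lower, upper)} of individual parameters.
#' @return A prior data frame with columns \code{name}, \code{lower},
#'   \code{upper}, \code{scale}.
#' @export
default_priors <- function(model, overrides = NULL) {
  info <- param_info(model)
  bounds <- t(vapply(seq_len(nrow(info)), function(i) {
    switch(info$kind[i],
           beta = , alpha = , deltap = , deltam = , kappa = c(-6, 1),
           K_tx = , K_deg = c(-5, 1),
           h_tx = , h_deg = c(1, 4),
           m0 = , p0 = c(-5, 1),
           sigma_tc = , sigma_ss = c(-2, 1),
           stop("unknown parameter kind: ", info$kind[i]))
  }, numeric(2)))
  prior <- data.frame(name = info$name, lower = bounds[, 1],
                      upper = bounds[, 2], scale = info$scale,
                      stringsAsFactors = FALSE)
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      i <- match(nm, prior$name)
      if (is.na(i))
        stop("prior override for unknown parameter: ", nm, call. = FALSE)
      b <- overrides[[nm]]
      if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2])
        stop("prior override for ", nm,
             " must be c(lower, upper) with lower < upper", call. = FALSE)
      prior$lower[i] <- b[1]
      prior$upper[i] <- b[2]
    }
  }
  prior
}

#' Transform linear-scale parameters to storage scale
#'
#' Parameters are stored on a log10 scale (except Hill exponents, kept
#' linear) for inference under log-uniform priors. \code{pack_log10} maps
#' strictly positive linear values to the storage scale;
#' \code{unpack_log10} inverts it. The two are exact inverses to machine
#' precision.
#'
#' @param linear Named numeric vector of linear-scale values covering
#'   every parameter of the model.
#' @param model A \code{cyclin_model}.
#' @return Named numeric vector on the storage scale, ordered as
#'   [param_info()].
#' @export
pack_log10 <- function(linear, model) {
  info <- param_info(model)
  miss <- setdiff(info$name, names(linear))
  if (length(miss) > 0)
    stop("missing parameter value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- linear[info$name]
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all linear-scale parameter values must be strictly positive and finite",
         call. = FALSE)
  out <- ifelse(info$scale == "log10", log10(x), x)
  names(out) <- info$name
  out
}

#' @rdname pack_log10
#' @param params Named numeric vector on the storage scale.
#' @export
unpack_log10 <- function(params, model) {
  info <- param_info(model)
  miss <- setdiff(info$name, names(params))
  if (length(miss) > 0)
    stop("missing parameter value(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- params[info$name]
  out <- ifelse(info$scale == "log10", 10^x, x)
  names(out) <- info$name
  out
}

#' Hill repression factor
#'
#' Multiplicative inhibition factor 1 / (1 + (conc / K)^h), monotone
#' non-increasing in the inhibitor concentration: 1 with no inhibitor,
#' 1/2 at the half-inhibition point conc = K, and 0 in the saturating
#' limit. Used both for inhibition of transcription and for inhibition of
#' protein degradation.
#'
#' @param conc Inhibitor (protein) concentration, uM; non-negative.
#' @param K Half-inhibition constant, uM; positive.
#' @param h Hill exponent; positive.
#' @return Factor in (0, 1].
#' @export
inhibition_factor <- function(conc, K, h) {
  if (any(K <= 0) || any(h <= 0))
    stop("K and h must be strictly positive", call. = FALSE)
  if (any(conc < 0))
    stop("inhibitor concentration must be non-negative", call. = FALSE)
  1 / (1 + (conc / K)^h)
}

# Pack model wiring + linear parameters into the flat numeric vector
# consumed by the C right-hand side. Layout (n = number of genes):
# [n, act[n], tinh[n], dinh[n], beta[n], alpha[n], deltap[n],
#  deltam, kappa, Ktx[n], htx[n], Kdeg[n], hdeg[n]]
# where indices are 1-based gene indices and 0 means "no inhibitor".
model_parms <- function(model, linear) {
  gn <- model$genes$name
  n <- length(gn)
  idx <- function(x) ifelse(is.na(x), 0L, match(x, gn))
  grab <- function(prefix, default = NA_real_) {
    v <- linear[paste0(prefix, "_", gn)]
    if (!is.na(default)) v[is.na(v)] <- default
    unname(v)
  }
  Ktx <- htx <- Kdeg <- hdeg <- rep(1, n)
  ti <- !is.na(model$genes$transcription_inhibitor)
  if (any(ti)) {
    Ktx[ti] <- linear[paste0("K_tx_", gn[ti])]
    htx[ti] <- linear[paste0("h_tx_", gn[ti])]
  }
  di <- !is.na(model$genes$degradation_inhibitor)
  if (any(di)) {
    Kdeg[di] <- linear[paste0("K_deg_", gn[di])]
    hdeg[di] <- linear[paste0("h_deg_", gn[di])]
  }
  c(n,
    idx(model$genes$activator),
    idx(model$genes$transcription_inhibitor),
    idx(model$genes$degradation_inhibitor),
    grab("beta"), grab("alpha"), grab("deltap"),
    unname(linear["deltam"]), unname(linear["kappa"]),
    Ktx, htx, Kdeg, hdeg)
}

#' Time derivatives of the model state
#'
#' Mass-action rate equations with Hill-type inhibition terms. For each
#' gene g with activator protein A, transcriptional inhibitor protein I
#' (optional) and degradation-inhibitor protein D (optional):
#' \deqn{dm_g/dt = (beta_g + alpha_g A) f(I; K, h) - deltam \, m_g}
#' \deqn{dP_g/dt = kappa \, m_g - deltap_g P_g \, f(D; K, h)}
#' where f is [inhibition_factor()] (identically 1 when the edge is
#' absent). The system is autonomous.
#'
#' @param state Named or unnamed numeric vector of species concentrations
#'   (uM), ordered as \code{model$species} (all mRNA, then all protein).
#' @param params Parameter vector on the storage scale (see
#'   [param_info()]).
#' @param model A \code{cyclin_model}.
#' @return Numeric vector of time derivatives (uM/s), same order.
#' @export
cyclin_rhs <- function(state, params, model) {
  if (length(state) != length(model$species))
    stop("state length (", length(state), ") does not match species count (",
         length(model$species), ")", call. = FALSE)
  linear <- unpack_log10(params, model)
  parms <- model_parms(model, linear)
  .Call(C_cyclin_rhs, as.numeric(state), as.numeric(parms))
}
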