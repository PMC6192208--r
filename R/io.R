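# Strict delimited readers/writers for the three dataset schemas, the
# truth file, posterior archives, run configuration, and SBML export.

check_cols <- function(df, needed, path) {
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    stop("file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
}

bad_rows <- function(cond, path, what) {
  if (any(cond))
    stop("file ", path, ", line(s) ",
         paste(utils::head(which(cond) + 1L, 5), collapse = ", "),
         ": ", what, call. = FALSE)
}

#' Read and write relative time-course datasets
#'
#' Delimited schema: \code{experiment}, \code{gene}, \code{time_min}
#' (minutes on the common 80-min scale, within [0, 160]),
#' \code{log_ratio}, and optionally \code{native_period_min}. Validation
#' errors name the offending line.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_time_course <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("experiment", "gene", "time_min", "log_ratio"), path)
  bad_rows(!is.finite(df$time_min), path, "non-numeric time_min")
  bad_rows(df$time_min < 0 | df$time_min > 160, path,
           "time_min outside [0, 160]")
  bad_rows(!is.finite(df$log_ratio), path, "non-finite log_ratio")
  df
}

#' @rdname read_time_course
#' @param data Data frame in the same schema.
#' @export
write_time_course <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write absolute steady-state datasets
#'
#' Delimited schema: \code{kind} ("mRNA" or "protein"), \code{gene},
#' \code{log10_conc_uM}, \code{source}. Multiple sources per species
#' enter the likelihood as independent records.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_steady_state <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("kind", "gene", "log10_conc_uM", "source"), path)
  bad_rows(!(df$kind %in% c("mRNA", "protein")), path,
           "kind must be 'mRNA' or 'protein'")
  bad_rows(!is.finite(df$log10_conc_uM), path, "non-finite log10_conc_uM")
  df
}

#' @rdname read_steady_state
#' @param data Data frame in the same schema.
#' @export
write_steady_state <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write validation rate tables
#'
#' Delimited schema: \code{kind} (\code{mrna_degradation},
#' \code{transcription}, \code{translation}), \code{gene}, \code{value}
#' (positive, linear scale), \code{units}, \code{source}.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_validation_rates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("kind", "gene", "value", "units", "source"), path)
  bad_rows(!(df$kind %in% c("mrna_degradation", "transcription",
                            "translation")), path,
           "unknown rate kind")
  bad_rows(!is.finite(df$value) | df$value <= 0, path,
           "value must be positive and finite")
  df
}

#' @rdname read_validation_rates
#' @param data Data frame in the same schema.
#' @export
write_validation_rates <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write ground-truth parameter files
#'
#' Schema: \code{parameter}, \code{value} (storage scale: log10 for all
#' parameters but the Hill exponents).
#'
#' @param path CSV file path.
#' @return Named parameter vector.
#' @export
read_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("parameter", "value"), path)
  bad_rows(!is.finite(df$value), path, "non-finite value")
  stats::setNames(df$value, df$parameter)
}

#' @rdname read_truth
#' @param truth Named parameter vector on the storage scale.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(data.frame(parameter = names(truth),
                              value = unname(truth)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read a posterior archive
#'
#' The archive is a directory holding \code{draws.csv} (one row per
#' subsampled cold-chain draw, one column per parameter, plus
#' \code{log_post}), \code{prior_draws.csv}, and \code{metadata.json}
#' (settings, seed, acceptance and swap summaries, round trips).
#'
#' @param fit A \code{pt_fit}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
write_posterior_archive <- function(fit, dir) {
  stopifnot(inherits(fit, "pt_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- as.data.frame(fit$draws)
  d$log_post <- fit$log_post
  utils::write.csv(d, file.path(dir, "draws.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(fit$prior_draws),
                   file.path(dir, "prior_draws.csv"), row.names = FALSE)
  meta <- list(settings = fit$settings,
               betas = fit$betas,
               swap_acceptance_rate = ifelse(fit$swap_attempt > 0,
                                             fit$swap_accept / fit$swap_attempt,
                                             NA),
               round_trips = fit$round_trips$total,
               round_trips_per_replica = fit$round_trips$per_replica,
               block_sizes = lengths(fit$plan$blocks))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(dir, "metadata.json"))
  invisible(dir)
}

#' @rdname write_posterior_archive
#' @export
read_posterior_archive <- function(dir) {
  d <- utils::read.csv(file.path(dir, "draws.csv"))
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"))
  list(draws = as.matrix(d[setdiff(names(d), "log_post")]),
       log_post = d$log_post,
       prior_draws = as.matrix(utils::read.csv(file.path(dir,
                                                         "prior_draws.csv"))),
       metadata = meta)
}

#' Write and read a model configuration file
#'
#' YAML document listing the variant, the gene table (activation and
#' inhibition edges), the period and the prior bounds; the pair of
#' functions round-trips losslessly.
#'
#' @param model A \code{cyclin_model}.
#' @param prior Prior data frame.
#' @param path Output YAML path.
#' @return Invisibly, \code{path}.
#' @export
write_model_config <- function(model, prior, path) {
  cfg <- list(
    variant = if (is.na(model$variant)) NULL else model$variant,
    period = model$period,
    genes = lapply(seq_len(nrow(model$genes)), function(i) {
      g <- model$genes[i, ]
      out <- list(name = g$name, activator = g$activator)
      if (!is.na(g$transcription_inhibitor))
        out$transcription_inhibitor <- g$transcription_inhibitor
      if (!is.na(g$degradation_inhibitor))
        out$degradation_inhibitor <- g$degradation_inhibitor
      out
    }),
    priors = stats::setNames(lapply(seq_len(nrow(prior)), function(i)
      c(prior$lower[i], prior$upper[i])), prior$name))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  genes <- do.call(rbind, lapply(cfg$genes, function(g)
    data.frame(name = g$name, activator = g$activator,
               transcription_inhibitor = g$transcription_inhibitor %||% NA_character_,
               degradation_inhibitor = g$degradation_inhibitor %||% NA_character_,
               stringsAsFactors = FALSE)))
  model <- model_spec(genes, variant = cfg$variant %||% NA_integer_,
                      period = cfg$period %||% 4800)
  prior <- default_priors(model, overrides = cfg$priors)
  list(model = model, prior = prior)
}

#' Read and validate a run configuration
#'
#' YAML schema: \code{variant} (1-4) or \code{model_config} (path);
#' optional \code{priors} (named lower/upper overrides), \code{fixed}
#' (named storage-scale values held fixed), \code{log_base}; a
#' \code{sampler} block (\code{n_chains}, \code{swap_prob},
#' \code{mh_steps}, \code{burn_in}, \code{n_iter}, \code{subsample},
#' \code{seed}); a \code{data} block with paths (\code{time_course},
#' \code{steady_state}, \code{validation_rates}, any subset); and
#' \code{output_dir}. Errors name the offending field; referenced data
#' paths must exist.
#'
#' @param path YAML config path.
#' @return Validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variant) && is.null(cfg$model_config))
    stop("config: need either 'variant' or 'model_config'", call. = FALSE)
  s <- cfg$sampler %||% list()
  cfg$sampler <- list(
    n_chains = s$n_chains %||% 32L,
    swap_prob = s$swap_prob %||% 0.99,
    mh_steps = s$mh_steps %||% 5L,
    burn_in = s$burn_in %||% 1250000L,
    n_iter = s$n_iter %||% 5000000L,
    subsample = s$subsample %||% 2500L,
    seed = s$seed %||% 1L)
  for (f in names(cfg$sampler))
    if (!is.numeric(cfg$sampler[[f]]) || cfg$sampler[[f]] <= 0)
      stop("config: sampler.", f, " must be a positive number", call. = FALSE)
  cfg$log_base <- cfg$log_base %||% "natural"
  if (!cfg$log_base %in% c("natural", "log2"))
    stop("config: log_base must be 'natural' or 'log2'", call. = FALSE)
  for (f in intersect(c("time_course", "steady_state", "validation_rates"),
                      names(cfg$data %||% list()))) {
    p <- cfg$data[[f]]
    if (!file.exists(p))
      stop("config: data.", f, " path does not exist: ", p, call. = FALSE)
  }
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg
}

# Build model + prior from a validated run config.
config_model <- function(cfg, base = dirname(attr(cfg, "path") %||% ".")) {
  if (!is.null(cfg$model_config)) {
    mc <- read_model_config(cfg$model_config)
    model <- mc$model
    prior <- default_priors(model, overrides = cfg$priors)
  } else {
    model <- build_model(cfg$variant)
    prior <- default_priors(model, overrides = cfg$priors)
  }
  list(model = model, prior = prior)
}

mathml_ci <- function(x) paste0("<ci> ", x, " </ci>")

mathml_inhibition <- function(protein, K, h) {
  sprintf(paste0("<apply><divide/><cn> 1 </cn><apply><plus/><cn> 1 </cn>",
                 "<apply><power/><apply><divide/>%s%s</apply>%s</apply>",
                 "</apply></apply>"),
          mathml_ci(protein), mathml_ci(K), mathml_ci(h))
}

#' Export a model as SBML Level 3
#'
#' Writes an SBML Level 3 core document with one compartment, two
#' species per gene (mRNA and protein, micromolar), all kinetic
#' parameters on the linear scale, and four reactions per gene
#' (transcription with any Hill inhibition in its kinetic law, mRNA
#' degradation, translation, protein degradation with any
#' degradation-inhibition factor), reproducing the rate equations of
#' [cyclin_rhs()] term by term. The document is well-formed XML and
#' follows the SBML L3 core schema structurally.
#'
#' @param model A \code{cyclin_model}.
#' @param params Parameter vector on the storage scale.
#' @param path Output file path (.xml).
#' @return Invisibly, \code{path}.
#' @export
export_sbml <- function(model, params, path) {
  linear <- unpack_log10(params, model)
  gn <- model$genes$name
  esc <- function(x) gsub("&", "&amp;", x)
  sp_xml <- paste(vapply(model$species, function(s) {
    init <- if (startsWith(s, "mRNA_"))
      linear[[paste0("m0_", sub("mRNA_", "", s))]]
    else linear[[paste0("p0_", sub("protein_", "", s))]]
    sprintf(paste0('      <species id="%s" compartment="cell" ',
                   'initialConcentration="%.15g" hasOnlySubstanceUnits="false" ',
                   'boundaryCondition="false" constant="false"/>'), s, init)
  }, character(1)), collapse = "\n")
  kin <- unpack_log10(params, model)
  pnames <- param_info(model)$name
  pnames <- pnames[!grepl("^(m0_|p0_|sigma_)", pnames)]
  par_xml <- paste(vapply(pnames, function(p)
    sprintf('      <parameter id="%s" value="%.15g" constant="true"/>',
            p, kin[[p]]), character(1)), collapse = "\n")

  reactions <- character(0)
  for (i in seq_len(nrow(model$genes))) {
    g <- gn[i]
    act <- model$genes$activator[i]
    ti <- model$genes$transcription_inhibitor[i]
    di <- model$genes$degradation_inhibitor[i]
    tx_terms <- sprintf(
      "<apply><plus/>%s<apply><times/>%s%s</apply></apply>",
      mathml_ci(paste0("beta_", g)), mathml_ci(paste0("alpha_", g)),
      mathml_ci(paste0("protein_", act)))
    if (!is.na(ti))
      tx_terms <- sprintf("<apply><times/>%s%s</apply>", tx_terms,
                          mathml_inhibition(paste0("protein_", ti),
                                            paste0("K_tx_", g),
                                            paste0("h_tx_", g)))
    mods <- c(paste0("protein_", act),
              if (!is.na(ti)) paste0("protein_", ti))
    reactions <- c(reactions, sbml_reaction(
      id = paste0("transcription_", g), products = paste0("mRNA_", g),
      modifiers = mods,
      math = sprintf("<apply><times/>%s%s</apply>", mathml_ci("cell"),
                     tx_terms)))
    reactions <- c(reactions, sbml_reaction(
      id = paste0("mrna_degradation_", g), reactants = paste0("mRNA_", g),
      math = sprintf("<apply><times/>%s%s%s</apply>", mathml_ci("cell"),
                     mathml_ci("deltam"), mathml_ci(paste0("mRNA_", g)))))
    reactions <- c(reactions, sbml_reaction(
      id = paste0("translation_", g), products = paste0("protein_", g),
      modifiers = paste0("mRNA_", g),
      math = sprintf("<apply><times/>%s%s%s</apply>", mathml_ci("cell"),
                     mathml_ci("kappa"), mathml_ci(paste0("mRNA_", g)))))
    deg_math <- sprintf("<apply><times/>%s%s%s</apply>", mathml_ci("cell"),
                        mathml_ci(paste0("deltap_", g)),
                        mathml_ci(paste0("protein_", g)))
    if (!is.na(di))
      deg_math <- sprintf("<apply><times/>%s%s</apply>", deg_math,
                          mathml_inhibition(paste0("protein_", di),
                                            paste0("K_deg_", g),
                                            paste0("h_deg_", g)))
    reactions <- c(reactions, sbml_reaction(
      id = paste0("protein_degradation_", g),
      reactants = paste0("protein_", g),
      modifiers = if (!is.na(di)) paste0("protein_", di),
      math = deg_math))
  }
  doc <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="%s" name="%s" timeUnits="second">
    <listOfCompartments>
      <compartment id="cell" spatialDimensions="3" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
%s
    </listOfSpecies>
    <listOfParameters>
%s
    </listOfParameters>
    <listOfReactions>
%s
    </listOfReactions>
  </model>
</sbml>',
    esc(sprintf("cyclin_network_variant_%s",
                ifelse(is.na(model$variant), "custom", model$variant))),
    "Yeast cyclin transcriptional regulation network",
    sp_xml, par_xml, paste(reactions, collapse = "\n"))
  xml2::read_xml(doc)  # well-formedness check before writing
  writeLines(doc, path)
  invisible(path)
}

sbml_reaction <- function(id, reactants = NULL, products = NULL,
                          modifiers = NULL, math) {
  lst <- function(tag, entries)
    if (length(entries) == 0) "" else
      sprintf("        <listOf%s>\n%s\n        </listOf%s>\n", tag,
              paste("         ", entries, collapse = "\n"), tag)
  spref <- function(ids)
    sprintf('<speciesReference species="%s" stoichiometry="1" constant="true"/>',
            ids)
  sprintf(paste0(
    '      <reaction id="%s" reversible="false">\n',
    '%s%s%s',
    '        <kineticLaw>\n',
    '          <math xmlns="http://www.w3.org/1998/Math/MathML">\n',
    '            %s\n',
    '          </math>\n',
    '        </kineticLaw>\n',
    '      </reaction>'),
    id,
    lst("Reactants", spref(reactants)),
    lst("Products", spref(products)),
    lst("Modifiers",
        sprintf('<modifierSpeciesReference species="%s"/>', modifiers)),
    math)
}

#' Structural summary of an exported SBML file
#'
#' Parses an SBML document and returns the species, parameter and
#' reaction inventory, used to verify that exports reproduce the model
#' structure (round-trip check).
#'
#' @param path SBML file path.
#' @return List with \code{species}, \code{parameters} (named values),
#'   \code{n_reactions}, \code{reaction_ids}.
#' @export
read_sbml_summary <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version2/core")
  sp <- xml2::xml_find_all(doc, ".//s:species", ns)
  pars <- xml2::xml_find_all(doc, ".//s:parameter", ns)
  rx <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  list(species = xml2::xml_attr(sp, "id"),
       initial = stats::setNames(as.numeric(xml2::xml_attr(sp, "initialConcentration")),
                                 xml2::xml_attr(sp, "id")),
       parameters = stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                                    xml2::xml_attr(pars, "id")),
       n_reactions = length(rx),
       reaction_ids = xml2::xml_attr(rx, "id"))
}
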