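#' Construct a metabolic model object
#'
#' A `metabolic_model` is the parsed, graph-agnostic form of a reaction
#' network: one row per reaction with reactant/product id lists, a
#' reversibility flag and an optional gene-protein-reaction (GPR) rule, plus
#' one row per metabolite. Stoichiometric coefficients are deliberately not
#' stored: the downstream method is purely topological.
#'
#' @param reactions tibble with columns `id` (chr), `reversible` (lgl),
#'   `reactants` (list of chr), `products` (list of chr) and optionally
#'   `gpr` (chr, boolean rule over gene ids using `and`/`or`).
#' @param metabolites optional tibble with columns `id` and optionally
#'   `compartment`, `boundary`. Missing metabolites referenced by reactions
#'   are added automatically.
#' @param id model identifier.
#' @param extracellular_suffix regex suffix marking extracellular metabolite
#'   ids (BiGG-style `"_e"` by default).
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, metabolites = NULL, id = "model",
                            extracellular_suffix = "_e$") {
  stopifnot(is.data.frame(reactions))
  reactions <- as_tibble(reactions)
  required <- c("id", "reversible", "reactants", "products")
  missing_cols <- setdiff(required, names(reactions))
  if (length(missing_cols) > 0) {
    abort(paste0("reactions is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"gpr" %in% names(reactions)) reactions$gpr <- NA_character_
  if (nrow(reactions) == 0) abort("model must contain at least one reaction")
  if (anyDuplicated(reactions$id)) {
    abort(paste0("duplicate reaction id(s): ",
                 paste(unique(reactions$id[duplicated(reactions$id)]),
                       collapse = ", ")))
  }
  reactions$reversible <- as.logical(reactions$reversible)
  reactions$reactants <- lapply(reactions$reactants, as.character)
  reactions$products <- lapply(reactions$products, as.character)

  referenced <- unique(c(unlist(reactions$reactants), unlist(reactions$products)))
  if (is.null(metabolites)) {
    metabolites <- tibble(id = referenced)
  } else {
    metabolites <- as_tibble(metabolites)
    undeclared <- setdiff(referenced, metabolites$id)
    if (length(undeclared) > 0) {
      offenders <- reactions$id[vapply(seq_len(nrow(reactions)), function(i) {
        any(c(reactions$reactants[[i]], reactions$products[[i]]) %in% undeclared)
      }, logical(1))]
      abort(paste0("reaction(s) reference undeclared metabolite(s): ",
                   paste(offenders, collapse = ", "),
                   " (unknown: ", paste(head(undeclared, 5), collapse = ", "), ")"))
    }
  }
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- NA_character_
  if (!"boundary" %in% names(metabolites)) metabolites$boundary <- FALSE
  metabolites$is_extracellular <-
    grepl(extracellular_suffix, metabolites$id) |
    metabolites$boundary |
    (!is.na(metabolites$compartment) & metabolites$compartment %in% c("e", "extracellular"))
  metabolites <- dplyr::arrange(metabolites, .data$id)
  reactions <- dplyr::arrange(reactions, .data$id)

  structure(
    list(id = id, reactions = reactions, metabolites = metabolites,
         genes = sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", sum(x$reactions$reversible), " reversible)\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites), "\n", sep = "")
  if (length(x$genes) > 0) cat("  genes:       ", length(x$genes), "\n", sep = "")
  invisible(x)
}

#' Read a model from the tabular reaction-list format
#'
#' The dialect is a UTF-8 TSV with a header row and columns `reaction_id`,
#' `reversible` (0/1), `reactants` and `products` (semicolon-separated
#' metabolite ids); an optional `gpr` column carries boolean gene rules.
#' An exchange reaction may leave one side empty.
#'
#' @param path file path.
#' @inheritParams metabolic_model
#' @return a [metabolic_model()].
#' @export
read_model_tsv <- function(path, id = tools::file_path_sans_ext(basename(path)),
                           extracellular_suffix = "_e$") {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("reaction_id", "reversible", "reactants", "products")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  split_ids <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(trimws(s))) character(0)
      else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  reactions <- tibble(
    id = tab$reaction_id,
    reversible = tab$reversible %in% c("1", "true", "TRUE"),
    reactants = split_ids(tab$reactants),
    products = split_ids(tab$products),
    gpr = if ("gpr" %in% names(tab)) tab$gpr else NA_character_
  )
  metabolic_model(reactions, id = id, extracellular_suffix = extracellular_suffix)
}

#' Write a model in the tabular reaction-list format
#'
#' Round-trips losslessly through [read_model_tsv()].
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model_tsv <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  join <- function(l) vapply(l, paste, character(1), collapse = ";")
  tab <- tibble(
    reaction_id = model$reactions$id,
    reversible = as.integer(model$reactions$reversible),
    reactants = join(model$reactions$reactants),
    products = join(model$reactions$products)
  )
  if (any(!is.na(model$reactions$gpr))) tab$gpr <- model$reactions$gpr
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a seed-metabolite list
#'
#' One metabolite id per line; blank lines and `#` comments are ignored.
#'
#' @param path file path.
#' @return character vector of metabolite ids.
#' @export
read_seeds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' @rdname read_seeds
#' @param seeds character vector of metabolite ids.
#' @export
write_seeds <- function(seeds, path) {
  writeLines(seeds, path)
  invisible(path)
}

#' Validate a model file
#'
#' Parses the file (TSV dialect or SBML, by extension), and reports structural
#' problems without mutating anything: unparsable rows, duplicate reaction
#' ids, empty reaction sides on non-exchange reactions, and whether exchange
#' reactions and GPR rules are detectable.
#'
#' @param path model file path.
#' @param exchange_prefix id prefix marking exchange reactions.
#' @return a tibble with columns `level` (`"info"`, `"warning"`, `"error"`)
#'   and `message`.
#' @export
validate_model <- function(path, exchange_prefix = "EX_") {
  notes <- list()
  note <- function(level, msg) notes[[length(notes) + 1]] <<- tibble(level = level, message = msg)
  if (!file.exists(path)) {
    return(tibble(level = "error", message = paste0("file not found: ", path)))
  }
  model <- tryCatch(read_model_auto(path), error = function(e) {
    note("error", conditionMessage(e))
    NULL
  })
  if (is.null(model)) return(dplyr::bind_rows(notes))
  note("info", paste0("parsed ", nrow(model$reactions), " reactions, ",
                      nrow(model$metabolites), " metabolites"))
  both_empty <- lengths(model$reactions$reactants) == 0 &
    lengths(model$reactions$products) == 0
  if (any(both_empty)) {
    note("error", paste0("reaction(s) with no reactants and no products: ",
                         paste(model$reactions$id[both_empty], collapse = ", ")))
  }
  one_empty <- xor(lengths(model$reactions$reactants) == 0,
                   lengths(model$reactions$products) == 0)
  is_ex <- detect_exchange(model, exchange_prefix)
  bad_boundary <- one_empty & !is_ex
  if (any(bad_boundary)) {
    note("warning", paste0("non-exchange reaction(s) with an empty side: ",
                           paste(model$reactions$id[bad_boundary], collapse = ", ")))
  }
  if (!any(is_ex)) {
    note("warning", "no exchange reactions detected; community joining would share nothing")
  } else {
    note("info", paste0(sum(is_ex), " exchange reaction(s) detected"))
  }
  if (all(is.na(model$reactions$gpr))) {
    note("warning", "no GPR rules present; gene knockouts are unavailable for this model")
  }
  dplyr::bind_rows(notes)
}

#' Read a model file by extension
#'
#' `.tsv`/`.txt` files go through [read_model_tsv()], `.xml`/`.sbml` through
#' [read_model_sbml()].
#'
#' @inheritParams read_model_tsv
#' @return a [metabolic_model()].
#' @export
read_model_auto <- function(path, extracellular_suffix = "_e$") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xml", "sbml")) {
    read_model_sbml(path, extracellular_suffix = extracellular_suffix)
  } else {
    read_model_tsv(path, extracellular_suffix = extracellular_suffix)
  }
}
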