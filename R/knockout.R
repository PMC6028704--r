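#' Simulate gene knockouts through GPR rules
#'
#' A reaction is removed exactly when its gene-protein-reaction rule
#' evaluates to `FALSE` with the listed genes set to `FALSE` and every other
#' gene set to `TRUE`. Reactions without a GPR rule are never removed.
#' Metabolites left without any reaction are retained as inert nodes, which
#' keeps downstream table indexing stable and is harmless to the traversal.
#'
#' @param model a [metabolic_model()].
#' @param gene_ids character vector of genes to knock out. Unknown ids
#'   produce a warning and are ignored.
#' @return a modified copy of `model`.
#' @export
knockout_genes <- function(model, gene_ids) {
  stopifnot(inherits(model, "metabolic_model"))
  gene_ids <- as.character(gene_ids)
  unknown <- setdiff(gene_ids, model$genes)
  if (length(unknown) > 0) {
    warn(paste0("unknown gene id(s), ignored: ", paste(unknown, collapse = ", ")))
  }
  off <- intersect(gene_ids, model$genes)
  keep <- vapply(model$reactions$gpr, gpr_eval, logical(1), off = off,
                 USE.NAMES = FALSE)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  if (nrow(model$reactions) == 0) abort("knockout removed every reaction in the model")
  model$genes <- sort(unique(unlist(lapply(model$reactions$gpr, gpr_genes))))
  model
}

# Gene ids appearing in a GPR rule string.
gpr_genes <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(rule)) return(character(0))
  toks <- gpr_tokens(rule)
  toks[!toks %in% c("(", ")", "and", "or")]
}

gpr_tokens <- function(rule) {
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  ifelse(tolower(toks) %in% c("and", "&", "&&"), "and",
         ifelse(tolower(toks) %in% c("or", "|", "||"), "or", toks))
}

# Evaluate a GPR rule with the genes in `off` set FALSE, all others TRUE.
gpr_eval <- function(rule, off) {
  if (is.null(rule) || is.na(rule) || !nzchar(rule)) return(TRUE)
  toks <- gpr_tokens(rule)
  expr <- vapply(toks, function(t) {
    switch(t,
           "(" = "(", ")" = ")", "and" = "&&", "or" = "||",
           if (t %in% off) "FALSE" else "TRUE")
  }, character(1))
  out <- tryCatch(eval(parse(text = paste(expr, collapse = " "))),
                  error = function(e) {
                    abort(paste0("unparsable GPR rule: ", rule))
                  })
  isTRUE(out)
}
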