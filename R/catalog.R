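#' Interaction-class specification
#'
#' A named bundle of per-agent speed parameters plus the shared global
#' dynamics parameters and the coupling rule joining the two agents.
#' The only coupling rule the model defines is that agent 2 takes
#' agent 1's instantaneous position as its goal; the field is kept as an
#' extension point.
#'
#' @param name class label (e.g. `"Chasing"`).
#' @param agent1,agent2 [agent_speed_params()] bundles.
#' @param global_params a [global_dynamics_params()]; classes may
#'   override the shared defaults.
#' @param coupling coupling-rule identifier.
#' @return An object of class `interaction_class_spec`.
#' @export
interaction_class_spec <- function(name, agent1, agent2,
                                   global_params = global_dynamics_params(),
                                   coupling = "agent2_goal_is_agent1_position") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("name must be a non-empty string")
  if (!inherits(agent1, "agent_speed_params") ||
      !inherits(agent2, "agent_speed_params"))
    stop("agent1 and agent2 must be agent_speed_params objects")
  if (!inherits(global_params, "global_dynamics_params"))
    stop("global_params must be a global_dynamics_params object")
  structure(list(name = name, agent1 = agent1, agent2 = agent2,
                 global_params = global_params, coupling = coupling),
            class = "interaction_class_spec")
}

.catalog_cols <- function() {
  fields <- c("k", "k_eps", "c5", "c6", "c7", "c8", "c9")
  c("name", paste0("agent1_", fields), paste0("agent2_", fields))
}

#' Load an interaction-class catalog
#'
#' Reads a catalog CSV (one row per class, the seven speed-drive
#' parameters of each agent in named columns) into a list of
#' [interaction_class_spec()] objects. The bundled default holds the
#' fifteen interaction classes with their reference parameter values.
#'
#' @param source path to a catalog CSV; defaults to the bundled catalog.
#' @param global_params shared [global_dynamics_params()] attached to
#'   every class.
#' @return A named list of `interaction_class_spec` objects.
#' @export
#' @examples
#' cat <- load_catalog()
#' length(cat)                  # 15
#' cat[["Chasing"]]$agent2$c7   # 7
load_catalog <- function(source = system.file("extdata",
                                              "interaction_classes.csv",
                                              package = "dyadsim"),
                         global_params = global_dynamics_params()) {
  df <- utils::read.csv(source, check.names = FALSE,
                        stringsAsFactors = FALSE)
  missing <- setdiff(.catalog_cols(), names(df))
  if (length(missing))
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("catalog class names must be unique; duplicated: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  fields <- c("k", "k_eps", "c5", "c6", "c7", "c8", "c9")
  specs <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    num <- function(prefix) {
      vals <- as.numeric(row[paste0(prefix, "_", fields)])
      if (any(is.na(vals)))
        stop("non-numeric value for class '", row$name, "' in ", prefix,
             " column(s)")
      names(vals) <- fields
      do.call(agent_speed_params, as.list(vals))
    }
    interaction_class_spec(row$name, num("agent1"), num("agent2"),
                           global_params = global_params)
  })
  names(specs) <- df$name
  specs
}

#' Write an interaction-class catalog
#'
#' Inverse of [load_catalog()]: the written file reads back to a
#' field-identical catalog.
#'
#' @param catalog a list of [interaction_class_spec()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  fields <- c("k", "k_eps", "c5", "c6", "c7", "c8", "c9")
  rows <- lapply(catalog, function(sp) {
    v1 <- unlist(sp$agent1[fields])
    v2 <- unlist(sp$agent2[fields])
    stats::setNames(
      data.frame(sp$name, t(v1), t(v2), stringsAsFactors = FALSE),
      .catalog_cols())
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' The bundled interaction-class catalog
#'
#' Convenience wrapper for [load_catalog()] with the bundled fifteen
#' classes: Avoiding, Bumping, Chasing, Dodging, Fighting, Flirting,
#' Following, Frightening, Guarding, Meeting, Playing, Pulling,
#' Pushing, Tug of War, Walking.
#'
#' @inheritParams load_catalog
#' @return A named list of 15 `interaction_class_spec` objects.
#' @export
interaction_catalog <- function(global_params = global_dynamics_params()) {
  load_catalog(global_params = global_params)
}
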