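#' @keywords internal
"_PACKAGE"

## Vocabulary the package recognises. Everything else in a file is carried
## opaquely as residual triples.

NS_BP3 <- "http://www.biopax.org/release/biopax-level3.owl#"
NS_BP2 <- "http://www.biopax.org/release/biopax-level2.owl#"
NS_RDF <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
NS_XSD <- "http://www.w3.org/2001/XMLSchema#"
NS_OWL <- "http://www.w3.org/2002/07/owl#"
## annotation namespace for statements this package adds (same-composition links)
NS_CFX <- "http://example.org/complexfix-annotations#"

RDF_TYPE <- paste0(NS_RDF, "type")

bp3 <- function(local) paste0(NS_BP3, local)

## BioPAX physical-entity classes -> entity kind
BP_ENTITY_KINDS <- c(
  "Protein"              = "protein",
  "SmallMolecule"        = "small-molecule",
  "Dna"                  = "dna",
  "DnaRegion"            = "dna",
  "Rna"                  = "rna",
  "RnaRegion"            = "rna",
  "Complex"              = "complex",
  "PhysicalEntity"       = "other-physical-entity",
  "SimplePhysicalEntity" = "other-physical-entity"
)

## Interaction classes whose instances are counted in the participation census
BP_INTERACTION_CLASSES <- c(
  "Interaction", "MolecularInteraction", "GeneticInteraction",
  "Control", "Catalysis", "Modulation", "TemplateReactionRegulation",
  "Conversion", "BiochemicalReaction", "ComplexAssembly", "Degradation",
  "Transport", "TransportWithBiochemicalReaction", "TemplateReaction"
)

## Participation properties counted, one hop only: the union of the BioPAX
## participation subproperties plus the generic participant property.
BP_PARTICIPATION_PROPS <- c(
  "left", "right", "controller", "cofactor", "product", "template",
  "participant"
)

## empty triple table; the uniform internal representation of RDF statements
empty_triples <- function() {
  tibble::tibble(
    subject   = character(),
    predicate = character(),
    object    = character(),
    obj_type  = character(),  # "iri", "literal" or "blank"
    datatype  = character(),
    lang      = character()
  )
}

triple <- function(subject, predicate, object, obj_type = "iri",
                   datatype = NA_character_, lang = NA_character_) {
  tibble::tibble(
    subject = subject, predicate = predicate, object = object,
    obj_type = obj_type, datatype = datatype, lang = lang
  )
}

literal_triple <- function(subject, predicate, value,
                           datatype = NA_character_) {
  triple(subject, predicate, as.character(value),
         obj_type = "literal", datatype = datatype)
}

## plain literals and xsd:string literals are the same thing in RDF 1.1;
## normalize so round trips through either dialect compare equal
normalize_triples <- function(tr) {
  xsd_string <- paste0(NS_XSD, "string")
  tr$datatype[tr$obj_type == "literal" &
                !is.na(tr$datatype) & tr$datatype == xsd_string] <-
    NA_character_
  tr
}

## canonical lexical form for stoichiometric coefficients (xsd:float style,
## matching Reactome's "2.0" convention); exact for integers, up to 15
## significant digits otherwise
format_coefficient <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15,
         sprintf("%.1f", x),
         vapply(x, function(v) format(v, digits = 15, scientific = FALSE),
                character(1)))
}

sort_triples <- function(tr) {
  dplyr::arrange(tr, .data$subject, .data$predicate, .data$object,
                 .data$obj_type)
}
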