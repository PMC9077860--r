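# Shared fixtures: parse once per test run.
parseOne <- function(smiles, id) {
  tmp <- tempfile(fileext = ".smi")
  writeLines(paste(smiles, id), tmp)
  on.exit(unlink(tmp))
  readSmiles(tmp)[[1]]
}

fixtureMols <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fixtureCompounds(asMolecules = TRUE)
    cache
  }
})

# formula as named count vector
formulaOf <- function(mol) {
  t <- table(atomTable(mol)$element)
  stats::setNames(as.integer(t), names(t))
}

# pure hydrocarbons in the curated set
HYDROCARBON_IDS <- c("1", "50", "54", "59")
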