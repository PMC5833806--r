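# Regenerates the shipped model-definition file from the programmatic
# generator. Run from the repository root after editing bcl2_model().
devtools::load_all(".", quiet = TRUE)
net <- bcl2_model()
stopifnot(length(net$species) == 71, length(net$reactions) == 126)
write_model_definition(net, "inst/extdata/bcl2_network_reconstructed.json")
cat("wrote inst/extdata/bcl2_network_reconstructed.json:",
    length(net$species), "species,", length(net$reactions), "reactions\n")
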