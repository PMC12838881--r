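variant	heavy_chain	cdrh3
A2	EVQLVESGGGLVKPGGSLRLSCAASGFTFSNAWMSWVRQAPGKGLEWVGRIKSKTDGGTTDYAAPVKGRFTISRDDSKNTLYLQMNSLKTEDTAVYYCARSYYEYVGFDYWGQGTLVTVSSGS	SYYEYVG
A4	EVQLVESGGGLVKPGGSLRLSCAASGFTFSNAWMSWVRQAPGKGLEWVGRIKSKTDGGTTDYAAPVKGRFTISRDDSKNTLYLQMNSLKTEDTAVYYCARPTSYYYFDYWGQGTLVTVSSGS	PTSYYY
A6	EVQLVQSGAEVKKPGESLKISCKGSGYSFTSYWIGWVRQMPGKGLEWMGIIYPGDSDTRYSPSFQGQVTISADKSISTAYLQWSSLKASDTAVYYCARTDLHVHVYYFDYWGQGTLVTVSSGS	TDLHVHVYY
A7	EVQLVQSGAEVKKPGESLKISCKGSGYSFTSYWIGWVRQMPGKGLEWMGIIYPGDSDTRYSPSFQGQVTISADKSISTAYLQWSSLKASDTAVYYCARKKEYYSRFDYWGQGTLVTVSSGS	KKEYYSR
A9	QLQLQESGPGLVKPSETLSLTCTVSGGSISSSSYYWGWIRQPPGKGLEWIGSIYYSGSTYYNPSLKSRVTISVDTSKNQFSLKLSSVTAADTAVYYCARPGGYYDMEYLYFDYWGQGTLVTVSSGS	PGGYYDMEYLY
A10	EVQLVESGGGLVKPGGSLRLSCAASGFTFSNAWMSWVRQAPGKGLEWVGRIKSKTDGGTTDYAAPVKGRFTISRDDSKNTLYLQMNSLKTEDTAVYYCARTYASTPMLDFDYWGQGTLVTVSSGS	TYASTPMLD
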