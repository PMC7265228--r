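# Recombination signal sequences of Bos taurus IGHD genes, clusters 2-4.
# 5' RSS elements are given in top-strand order (nonamer, spacer, heptamer;
# heptamer adjacent to the coding region); 3' RSS in top-strand order
# (heptamer, spacer, nonamer). Lowercase, as published.
gene	cluster	rss5_nonamer	rss5_spacer	rss5_heptamer	rss3_heptamer	rss3_spacer	rss3_nonamer
IGHD1-2	2	ggattttga	gggtgtgcgtgt	caccctg	cacagtg	actcaggccctg	acataaagt
IGHD1-3	3	ggattttga	gggtgtgcgtgt	caccgtg	cacagtg	actcaggccctg	acataaagt
IGHD1-4	4	ggattttga	gggtgtgcgtgt	caccgtg	cacagtg	actcaggccctg	acataaagt
IGHD2-2	2	gctttttgc	caagggctctac	tgcggtg	cacagtg	agacatggggca	gcaaaccct
IGHD2-3	3	gctttttgc	caagggctctac	tgcggtg	cacagtg	agacatggggca	gcaaaccct
IGHD2-4	4	gctttttgc	caagggctctac	tgcggtg	cacagtg	agacatggggca	gcaaaccct
IGHD3-3	3	ggtttctga	tgccggctgtgt	cacggtg	cacagtg	acactgtccagg	acagaaacc
IGHD3-4	4	ggtttctga	tgccggctgtgt	cacggtg	cacagtg	acactgtccagg	acagaaacc
IGHD7-3	3	ggtttttga	tgccggctgtgt	cacggtg	cacagtg	atactctctggg	acaaaaacc
IGHD7-4	4	ggtttttga	tgccggctgtgt	cacggtg	cacagtg	atactctctggg	acaaaaacc
IGHD8-2	2	ggtttctga	tgccggctgtgt	cacggtg	cacagtg	atactctctggg	acaaaaacc
IGHD5-2	2	ggtttctga	tgccggctgtgt	tgtggtg	cacagtg	atgctctcagtg	tcagaaacc
IGHD5-3	3	ggtttctga	tgccggctgtgt	tgtggtg	cacagtg	acgctctcagtg	tcagaaacc
IGHD5-4	4	ggtttctga	tgccggctgtgt	tgtggtg	cacagtg	acgctctcagtg	tcagaaacc
IGHD6-2	2	ggtttctga	tgccggctgtgt	cacggtg	cacagtg	acactctctggg	acaaaaacc
IGHD6-3	3	ggtttctga	tgccagctgtgt	cacggtg	cacagtg	acactctctggg	acaaaaacc
IGHD6-4	4	ggtttctga	tgccagctgtgt	cacggtg	cacagtg	acactctctggg	acaaaaacc
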