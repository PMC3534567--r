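center	chromosomes	named_missed	annotated_genes	total_mbp
JGI	563	1463	1830805	2058.6
TIGR	95	852	254484	273.9
JCVI	68	190	179284	190.1
Sanger	67	892	205667	227.7
Others	781	10205	2105188	2276.6
Total	1574	13602	4575428	5026.9
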