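# Built-in CYP2C19 haplotype definition table.
star_name	gene	structural_kind	switch_interval	tandem_partners	activity	rs12248560	rs28399504	rs41291556	rs72552267	rs17884712	rs374036992	rs4986893	rs6413438	rs4244285	rs56337013	rs72558186
*1	CYP2C19	full_gene			1	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
*2	CYP2C19	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	var	ref	ref
*3	CYP2C19	full_gene			0	ref	ref	ref	ref	ref	ref	var	ref	ref	ref	ref
*4	CYP2C19	full_gene			0	ref	var	ref	ref	ref	ref	ref	ref	ref	ref	ref
*5	CYP2C19	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	ref	var	ref
*6	CYP2C19	full_gene			0	ref	ref	ref	var	ref	ref	ref	ref	ref	ref	ref
*7	CYP2C19	full_gene			0	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref	var
*8	CYP2C19	full_gene			0	ref	ref	var	ref	ref	ref	ref	ref	ref	ref	ref
*9	CYP2C19	full_gene			0.5	ref	ref	ref	ref	var	ref	ref	ref	ref	ref	ref
*10	CYP2C19	full_gene			0.5	ref	ref	ref	ref	ref	ref	ref	var	ref	ref	ref
*17	CYP2C19	full_gene			1.5	var	ref	ref	ref	ref	ref	ref	ref	ref	ref	ref
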