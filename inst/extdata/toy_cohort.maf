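Hugo_Symbol	Tumor_Sample_Barcode	Variant_Classification	VAF	purity	ploidy	CNV_CCF	CADD
G0003	P001	Splice_Site	0.41600350578028816	0.8769735440167092	2	NA	27.87697950264809
G0007	P001	Silent	0.42326067492489083	0.8769735440167092	2	NA	2.483905783492763
G0007	P001	Missense_Mutation	0.39361872344155846	0.8769735440167092	2	NA	8.16955174905781
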