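subject,kind,predicate,object
phosphorylation of 3-PGA,type,MetabolicTransference,
Mg-ATP,type,Non-geneProduct,
3-Phosphoglycerate,type,Non-geneProduct,
Mg-ADP,type,Non-geneProduct,
"1,3-Biphosphoglycerate",type,Non-geneProduct,
Phosphoglycerate kinase 1,type,GeneProduct,
Phosphoglycerate kinase activity,type,KinaseActivity,
phosphorylation of 3-PGA,property,has_input,Mg-ATP
phosphorylation of 3-PGA,property,has_input,3-Phosphoglycerate
phosphorylation of 3-PGA,property,has_output,Mg-ADP
phosphorylation of 3-PGA,property,has_output,"1,3-Biphosphoglycerate"
phosphorylation of 3-PGA,property,mediated_by,Phosphoglycerate kinase 1
phosphorylation of 3-PGA,property,requires,Phosphoglycerate kinase activity
# the spontaneous complexation that decomposes Mg-ATP into its subcomponents
ATP,type,Non-geneProduct,
Mg2+,type,Non-geneProduct,
complexation of ATP and Mg2+,type,SpontaneousComplexation,
complexation of ATP and Mg2+,property,has_input,ATP
complexation of ATP and Mg2+,property,has_input,Mg2+
complexation of ATP and Mg2+,property,has_output,Mg-ATP
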