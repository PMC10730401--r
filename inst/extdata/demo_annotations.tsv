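gene	go_id	go_name	ontology
Atg5	GO:0000045	autophagosome assembly	BP
Atg7	GO:0000045	autophagosome assembly	BP
Atg12	GO:0000045	autophagosome assembly	BP
Map1lc3b	GO:0016236	macroautophagy	BP
Sqstm1	GO:0016236	macroautophagy	BP
Lamp2	GO:0061684	chaperone-mediated autophagy	BP
Rab7b	GO:0010506	regulation of autophagy	BP
Rubcnl	GO:0010506	regulation of autophagy	BP
Trim30a	GO:0010506	regulation of autophagy	BP
Ulk1	GO:0000045	autophagosome assembly	BP
Tnf	GO:0006954	inflammatory response	BP
Il1b	GO:0006954	inflammatory response	BP
Ccl3	GO:0006954	inflammatory response	BP
Ccl5	GO:0006954	inflammatory response	BP
Trem2	GO:0050727	regulation of inflammatory response	BP
Nlrp3	GO:0050727	regulation of inflammatory response	BP
C4b	GO:0006954	inflammatory response	BP
Ndufa1	GO:0007005	mitochondrion organization	BP
Ndufa2	GO:0007005	mitochondrion organization	BP
Sdha	GO:0006099	tricarboxylic acid cycle	BP
Uqcrb	GO:0005743	mitochondrial inner membrane	CC
Cox7c	GO:0005743	mitochondrial inner membrane	CC
Cox8b	GO:0005743	mitochondrial inner membrane	CC
mt-Atp6	GO:0042775	mitochondrial ATP synthesis coupled electron transport	BP
mt-Atp8	GO:0042775	mitochondrial ATP synthesis coupled electron transport	BP
mt-Nd4	GO:0032981	mitochondrial respiratory chain complex I assembly	BP
Pdha1	GO:0006086	acetyl-CoA biosynthetic process from pyruvate	BP
Syp	GO:0036465	synaptic vesicle recycling	BP
Psd95	GO:0098839	postsynaptic density membrane	CC
Apoe	GO:0006869	lipid transport	BP
Ide	GO:0042447	hormone catabolic process	BP
Chrna4	GO:0007271	synaptic transmission, cholinergic	BP
Vamp8	GO:0006906	vesicle fusion	BP
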