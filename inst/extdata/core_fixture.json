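{"id":"core_fixture","metabolites":[{"id":"glc_e","compartment":"e"},{"id":"pyr_c","compartment":"c"},{"id":"ace_c","compartment":"c"},{"id":"ace_e","compartment":"e"},{"id":"glyc_c","compartment":"c"},{"id":"glyc_e","compartment":"e"},{"id":"pre1_c","compartment":"c"},{"id":"pre2_c","compartment":"c"},{"id":"atp_c","compartment":"c"},{"id":"o2_e","compartment":"e"},{"id":"co2_e","compartment":"e"}],"reactions":[{"id":"EX_glc_e","metabolites":{"glc_e":-1},"lower_bound":-10,"upper_bound":1000,"gene_reaction_rule":"","subsystem":"exchange"},{"id":"GPTS","metabolites":{"glc_e":-1,"pyr_c":2,"atp_c":2},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"gA1 and gA2","subsystem":"glycolysis"},{"id":"TCA","metabolites":{"pyr_c":-1,"atp_c":5,"o2_e":-2.5,"co2_e":3},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"gB1 and (gB2 or gB3)","subsystem":"citric acid cycle"},{"id":"POX","metabolites":{"pyr_c":-1,"ace_c":1,"atp_c":0.6,"co2_e":1},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"gC1","subsystem":"overflow"},{"id":"ACEt","metabolites":{"ace_c":-1,"ace_e":1},"lower_bound":-1000,"upper_bound":1000,"gene_reaction_rule":"gD1 or gD2","subsystem":"transport"},{"id":"ACS","metabolites":{"pyr_c":1,"ace_c":-1,"atp_c":-2,"co2_e":-1},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"gE1","subsystem":"anaplerotic"},{"id":"PRE1","metabolites":{"pyr_c":-2,"pre1_c":1,"atp_c":-1},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"gF1","subsystem":"biosynthesis"},{"id":"PRE2","metabolites":{"pyr_c":-1,"pre2_c":1,"atp_c":-1},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"gF2","subsystem":"biosynthesis"},{"id":"GLPS","metabolites":{"pyr_c":-1,"glyc_c":1,"atp_c":-1},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"gG1","subsystem":"overflow"},{"id":"GLPt","metabolites":{"glyc_c":-1,"glyc_e":1},"lower_bound":-1000,"upper_bound":1000,"gene_reaction_rule":"gG2 or gG3","subsystem":"transport"},{"id":"GLYCk","metabolites":{"pyr_c":1,"glyc_c":-1},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"gG4","subsystem":"alternate carbon"},{"id":"ATPM","metabolites":{"atp_c":-1},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"","subsystem":"maintenance","demand":true},{"id":"BIOMASS","metabolites":{"pre1_c":-2,"pre2_c":-2,"atp_c":-10},"lower_bound":0,"upper_bound":1000,"gene_reaction_rule":"","subsystem":"biomass","objective_coefficient":1},{"id":"EX_ace_e","metabolites":{"ace_e":-1},"lower_bound":-1000,"upper_bound":1000,"gene_reaction_rule":"","subsystem":"exchange"},{"id":"EX_glyc_e","metabolites":{"glyc_e":-1},"lower_bound":-1000,"upper_bound":1000,"gene_reaction_rule":"","subsystem":"exchange"},{"id":"EX_o2_e","metabolites":{"o2_e":-1},"lower_bound":-1000,"upper_bound":1000,"gene_reaction_rule":"","subsystem":"exchange"},{"id":"EX_co2_e","metabolites":{"co2_e":-1},"lower_bound":-1000,"upper_bound":1000,"gene_reaction_rule":"","subsystem":"exchange"}]}
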