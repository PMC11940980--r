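drug_code,generic_name,drug_class,substitution_group,maintenance_eligible,default_runout_days
J9271,pembrolizumab,ICI,,FALSE,21
J9299,nivolumab,ICI,,FALSE,21
J9228,ipilimumab,ICI,,FALSE,21
J9022,atezolizumab,ICI,,FALSE,21
J9173,durvalumab,ICI,,FALSE,21
J9119,cemiplimab,ICI,,FALSE,21
J9045,carboplatin,PLATINUM,platinum_agent,FALSE,21
J9060,cisplatin,PLATINUM,platinum_agent,FALSE,21
J9263,oxaliplatin,PLATINUM,platinum_agent,FALSE,21
J9267,paclitaxel,NONPLAT_CHEMO,paclitaxel_taxane,FALSE,21
J9264,nab-paclitaxel,NONPLAT_CHEMO,paclitaxel_taxane,FALSE,21
J9171,docetaxel,NONPLAT_CHEMO,,FALSE,21
J9305,pemetrexed,NONPLAT_CHEMO,,TRUE,21
J9201,gemcitabine,NONPLAT_CHEMO,,FALSE,21
J9390,vinorelbine,NONPLAT_CHEMO,,FALSE,21
J9206,irinotecan,NONPLAT_CHEMO,,FALSE,21
J9181,etoposide,NONPLAT_CHEMO,,FALSE,21
J9000,doxorubicin,NONPLAT_CHEMO,,FALSE,21
J9190,fluorouracil,NONPLAT_CHEMO,,FALSE,21
J8530,cyclophosphamide,NONPLAT_CHEMO,,FALSE,21
J9035,bevacizumab,VEGF,,TRUE,21
J9308,ramucirumab,VEGF,,FALSE,21
NDC-OSIM,osimertinib,TARGETED,,FALSE,30
NDC-ALEC,alectinib,TARGETED,,FALSE,30
NDC-SOTO,sotorasib,TARGETED,,FALSE,30
NDC-ERLO,erlotinib,TARGETED,,FALSE,30
NDC-CRIZ,crizotinib,TARGETED,,FALSE,30
NDC-LARO,larotrectinib,TARGETED,,FALSE,30
NDC-AFAT,afatinib,TARGETED,,FALSE,30
NDC-DABR,dabrafenib,TARGETED,,FALSE,30
J9351,topotecan,SCLC_TYPICAL,,FALSE,21
J9223,lurbinectedin,SCLC_TYPICAL,,FALSE,21
RX-STAT,atorvastatin,OTHER,,FALSE,30
RX-METF,metformin,OTHER,,FALSE,30
RX-LISI,lisinopril,OTHER,,FALSE,30
RX-OMEP,omeprazole,OTHER,,FALSE,30
RX-LEVO,levothyroxine,OTHER,,FALSE,30
RX-ONDA,ondansetron,OTHER,,FALSE,30
RX-DEXA,dexamethasone,OTHER,,FALSE,30
RX-FILG,filgrastim,OTHER,,FALSE,30
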