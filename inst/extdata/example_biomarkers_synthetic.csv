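subject_id,group,value_pg_ml
nc_0001,nc,453.604079312607
nc_0002,nc,165.874601820721
nc_0003,nc,458.880280286398
nc_0004,nc,296.366924703164
nc_0005,nc,269.819416715389
nc_0006,nc,493.777921570071
nc_0007,nc,520.773375082321
nc_0008,nc,421.420986014478
nc_0009,nc,403.147980114437
nc_0010,nc,414.561748696999
nc_0011,nc,326.292179558591
nc_0012,nc,586.149482630058
nc_0013,nc,394.717227202092
nc_0014,nc,477.702677463326
nc_0015,nc,527.286357439745
nc_0016,nc,95.3873630682564
nc_0017,nc,223.341305617571
nc_0018,nc,264.237002558487
nc_0019,nc,396.380502132501
dc_0001,dc,297.131236548222
dc_0002,dc,527.247065294775
dc_0003,dc,495.654589108492
dc_0004,dc,374.711246270319
dc_0005,dc,698.595071431828
dc_0006,dc,414.101508051359
dc_0007,dc,279.394733150056
dc_0008,dc,225.816670691728
dc_0009,dc,272.826245417325
dc_0010,dc,409.775644206377
dc_0011,dc,190.893152790236
MCI_0001,MCI,993.855471866603
MCI_0002,MCI,1318.62363173177
MCI_0003,MCI,1001.97816348749
MCI_0004,MCI,2982.62249411338
MCI_0005,MCI,745.399047786376
MCI_0006,MCI,1283.03789696052
MCI_0007,MCI,855.223775027439
MCI_0008,MCI,236.400558504739
MCI_0009,MCI,1122.08850311841
MCI_0010,MCI,699.066881030153
MCI_0011,MCI,1254.02368422628
MCI_0012,MCI,719.242357754741
MCI_0013,MCI,593.73100324537
MCI_0014,MCI,1423.57951968354
MCI_0015,MCI,1115.78995003104
MCI_0016,MCI,450.054895322107
MCI_0017,MCI,934.748042825598
MCI_0018,MCI,1009.54107281136
MCI_0019,MCI,2112.99002879075
MCI_0020,MCI,579.089461876832
MCI_0021,MCI,444.807267530516
AD_0001,AD,1315.99548317284
AD_0002,AD,340.456607807349
AD_0003,AD,387.675405168002
AD_0004,AD,612.321811286424
AD_0005,AD,312.03341980152
AD_0006,AD,319.494326697943
AD_0007,AD,272.678862203476
AD_0008,AD,320.182262811927
AD_0009,AD,763.671247868879
AD_0010,AD,1237.32626768063
AD_0011,AD,620.151528709869
AD_0012,AD,396.755251842709
AD_0013,AD,152.173916341791
AD_0014,AD,683.100832250736
AD_0015,AD,485.340228481586
AD_0016,AD,390.426556756823
AD_0017,AD,940.316996989166
AD_0018,AD,316.356490630395
AD_0019,AD,552.709837965571
AD_0020,AD,611.568262735369
AD_0021,AD,332.640928726252
AD_0022,AD,367.898790731364
AD_0023,AD,225.560597775018
AD_0024,AD,639.418034069237
AD_0025,AD,405.763275715602
AD_0026,AD,470.835399134928
AD_0027,AD,505.157792129013
AD_0028,AD,512.070316278493
AD_0029,AD,357.54753943625
AD_0030,AD,548.344007141733
AD_0031,AD,983.08348324496
AD_0032,AD,1031.71733783541
AD_0033,AD,439.844263024281
AD_0034,AD,555.880993351264
AD_0035,AD,505.7827468322
AD_0036,AD,1016.43016624679
AD_0037,AD,428.295410919856
AD_0038,AD,781.589753111586
AD_0039,AD,802.700742605505
AD_0040,AD,1258.43956003411
AD_0041,AD,572.235303007495
AD_0042,AD,201.930162599301
AD_0043,AD,384.212302993187
AD_0044,AD,1383.96243937529
AD_0045,AD,670.959443925705
AD_0046,AD,751.884596005377
AD_0047,AD,662.501329948952
AD_0048,AD,494.551245044186
AD_0049,AD,566.27200293314
AD_0050,AD,855.475896217378
AD_0051,AD,934.577350382599
AD_0052,AD,735.751816803779
AD_0053,AD,403.947114452578
AD_0054,AD,389.327708746787
AD_0055,AD,521.634089712801
AD_0056,AD,840.458380077168
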