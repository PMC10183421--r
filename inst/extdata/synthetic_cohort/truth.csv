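subject_id,side,shape_class_true,aspect_ratio_true,aspect_ratio_drawn,anterolateral_true_mm,posterolateral_true_mm,ap_width_mm,ml_depth_mm,patient_height_cm,height_from_plafond_mm,height_from_tip_mm,injured_height_from_plafond_mm,injured_height_from_tip_mm,tunnel_diameter_mm
S001,right,triangular_convex,1.0506529928814463,1.0506529928814454,19.974452487964722,19.011464892118383,29.47785284597388,12.750129774215582,165.75136740608087,15.482463073265606,45.54940652141229,20.245751204676775,51.3343376730574,3.5
S002,left,triangular_convex,0.8002567604358729,0.8002567604358728,16.332726180040794,20.409357330695848,24.426421312341205,13.530960650217926,168.28936343976878,15.901472729944908,42.8827890955949,30.851363266591804,60.46654801124853,3.5
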