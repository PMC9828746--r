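chemical_id,matrix,day,conc,loq,mdl,plot_type,valid
trisiloxane_317,forager_pollen,1,76.2,0.400,0.0713,treated,TRUE
trisiloxane_317,forager_pollen,10,6.77,0.400,0.0713,treated,TRUE
trisiloxane_317,forager_nectar,10,2.12,0.400,0.0634,treated,TRUE
trisiloxane_317,forager_nectar,0,<0.0634,0.400,0.0634,treated,TRUE
trisiloxane_317,stored_nectar,7,0.177,0.400,0.0634,treated,TRUE
trisiloxane_317,stored_nectar,0,<0.0634,0.400,0.0634,treated,TRUE
trisiloxane_317,bee_bread,7,40.5,0.400,0.0954,treated,TRUE
trisiloxane_317,bee_bread,0,<0.0954,0.400,0.0954,treated,TRUE
trisiloxane_317,larvae,7,0.768,0.400,0.0666,treated,TRUE
trisiloxane_317,larvae,0,<0.0666,0.400,0.0666,treated,TRUE
trisiloxane_317,wax,7,12.1,0.320,0.0688,treated,TRUE
trisiloxane_317,wax,0,<0.0688,0.320,0.0688,treated,TRUE
trisiloxane_317,whole_bees,7,8.32,0.400,0.0509,treated,TRUE
trisiloxane_317,whole_bees,0,<0.0509,0.400,0.0509,treated,TRUE
trisiloxane_317,forager_pollen,0,<0.0713,0.400,0.0713,control,TRUE
trisiloxane_OH,forager_pollen,0,26.5,0.100,0.0152,treated,TRUE
trisiloxane_OH,forager_pollen,10,0.163,0.100,0.0152,treated,TRUE
trisiloxane_OH,forager_nectar,7,0.48,0.100,0.0143,treated,TRUE
trisiloxane_OH,forager_nectar,0,0.0213,0.100,0.0143,treated,TRUE
trisiloxane_OH,stored_nectar,10,0.0662,0.100,0.0143,treated,TRUE
trisiloxane_OH,stored_nectar,0,<0.0143,0.100,0.0143,treated,TRUE
trisiloxane_OH,bee_bread,1,17.3,0.100,0.0100,treated,TRUE
trisiloxane_OH,bee_bread,10,2.99,0.100,0.0100,treated,TRUE
trisiloxane_OH,larvae,10,0.147,0.100,0.0207,treated,TRUE
trisiloxane_OH,larvae,0,<0.0207,0.100,0.0207,treated,TRUE
trisiloxane_OH,wax,7,1.22,0.100,0.0148,treated,TRUE
trisiloxane_OH,wax,0,<0.0148,0.100,0.0148,treated,TRUE
trisiloxane_OH,whole_bees,7,2.45,0.100,0.0168,treated,TRUE
trisiloxane_OH,whole_bees,0,<0.0168,0.100,0.0168,treated,TRUE
trisiloxane_OH,forager_pollen,0,<0.0152,0.100,0.0152,control,TRUE
trisiloxane_acetoxy,forager_pollen,0,4.53,0.100,0.0151,treated,TRUE
trisiloxane_acetoxy,forager_pollen,10,0.112,0.100,0.0151,treated,TRUE
trisiloxane_acetoxy,forager_nectar,0,<0.0119,0.100,0.0119,treated,TRUE
trisiloxane_acetoxy,forager_nectar,7,<0.0119,0.100,0.0119,treated,TRUE
trisiloxane_acetoxy,stored_nectar,0,<0.0119,0.100,0.0119,treated,TRUE
trisiloxane_acetoxy,stored_nectar,7,<0.0119,0.100,0.0119,treated,TRUE
trisiloxane_acetoxy,bee_bread,1,2.65,0.100,0.0072,treated,TRUE
trisiloxane_acetoxy,bee_bread,10,0.545,0.100,0.0072,treated,TRUE
trisiloxane_acetoxy,larvae,0,<0.0138,0.100,0.0138,treated,TRUE
trisiloxane_acetoxy,larvae,7,<0.0138,0.100,0.0138,treated,TRUE
trisiloxane_acetoxy,wax,10,0.332,0.100,0.0109,treated,TRUE
trisiloxane_acetoxy,wax,0,<0.0109,0.100,0.0109,treated,TRUE
trisiloxane_acetoxy,whole_bees,0,<0.0131,0.100,0.0131,treated,FALSE
trisiloxane_acetoxy,forager_pollen,0,<0.0151,0.100,0.0151,control,TRUE
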